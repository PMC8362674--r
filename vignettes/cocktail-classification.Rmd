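---
title: "Formalized vegetation classification with vegcocktail: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formalized vegetation classification with vegcocktail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegcocktail)
```

## The problem

Ephemeral wetland vegetation of the Isoëto-Nanojuncetea class — annual,
pioneer dwarf-rush and dwarf-cyperaceous communities of drying pond
bottoms, river banks and wet field depressions — is notoriously hard to
classify: stands are species-poor, short-lived, and share many species
with neighbouring vegetation classes. Expert-system ("Cocktail")
classification replaces subjective assignment with *formal definitions*:
boolean formulas over species groups and cover thresholds that decide,
identically for any data set, whether a relevé belongs to a syntaxon.
`vegcocktail` implements that workflow end to end: relevé I/O and
filtering, the definition language and unequivocal hierarchical
classifier, fidelity-based synoptic tables, geographic stratified
resampling, and detrended correspondence analysis with indicator-value
supplements — plus a labelled synthetic generator so every stage is
testable without database access.

## Data model and conventions

A `releve_table` holds long-format records (`plot_id`, `taxon`, `layer`,
`cover` as a fraction) plus a plot header (WGS84 lon/lat, area in m²,
date). Three conventions apply throughout:

* **Cover pooling.** Whenever covers of one species in several layers, of
  taxa merged into an aggregate, or of the members of a total-cover group
  must be combined, the independence rule `1 − Π(1 − cᵢ)` is used. Using
  one rule everywhere makes layer pooling, taxon merging and the `#TC`
  operator commute; 50 % + 50 % gives 75 %, and covers can never exceed
  100 %.
* **Name matching.** Taxon and group names match after whitespace
  collapsing and case folding — never fuzzily. Determinism beats
  convenience here; misspellings should be fixed by a merge map, not
  guessed at.
* **Cover codes.** The default Braun-Blanquet midpoint table is
  r → 0.1 %, + → 0.5 %, 1 → 2.5 %, 2 → 15 %, 3 → 37.5 %, 4 → 62.5 %,
  5 → 87.5 %. Source surveys rarely state their dialect, so the scale is
  an explicit, replaceable object (`cover_scale()`, YAML-loadable) rather
  than a hidden constant.

Plot filters mirror standard survey practice: relevés without coordinates
or with area outside [1, 100] m² are excluded (bounds inclusive, reading
"smaller than 1 m²"/"greater than 100 m²" literally), and cultivated
species are removed from the surviving plots without discarding the plots
themselves.

## The formal-definition engine

The formula grammar is small:

```
atom  := TC(group) > t | SC(group) > t | COV(taxon) > t | SOC(group)
expr  := atoms combined with AND, OR, NOT and parentheses
```

`TC` is the pooled total cover of the group members present, `SC` the
highest single-member cover, `COV` one species' cover, and `SOC` the
presence of a sociological group. Two points were genuinely open and are
resolved as package decisions:

* **Sociological-group presence.** The threshold is *at least half the
  members, rounded up* (`ceiling(n/2)`), overridable per group and per
  call. This matches common Cocktail practice for small (3–4 member)
  groups: two co-occurring members signal the community.
* **Conflict policy.** Classification is unequivocal: association
  definitions are evaluated first (in name order, so conflict reports are
  deterministic); a unique match assigns the association *and* its
  ancestors. When several definitions of a rank match, the relevé is
  flagged as a conflict, left unassigned at that rank, and falls back to
  the next rank up — so every relevé is assigned to at most one unit per
  rank, and assigned ranks always form a root-anchored path.

The packaged definition set (`syntaxa_reconstructed.yaml`) is labelled a
*reconstruction*. Its structure — class and alliance membership by
total-cover groups, association membership by the alliance total-cover
group combined with a sociological group or a single-species cover — is
the published multilevel design, but the published threshold file itself
is not reproduced here, so numeric thresholds were chosen once as package
defaults: class `TC > 5`, alliance `TC > 10` (membership thresholds), and
association-level species-cover thresholds of `> 5` (presence with
appreciable cover) or `> 25` where the unit is defined by dominance of one
species (Cyperetum micheliani, Cyperetum flavescentis). Comparators are
strict `>`. A membership threshold of 25 % total cover would reject many
genuine but sparse ephemeral stands — these communities often cover a few
percent of a plot — hence the lower class/alliance values. All thresholds
live in one editable YAML file; nothing is hard-coded.

## Fidelity statistics and species roles

For species *s* and unit *u* in a labelled set of *N* relevés (*Np* in
*u*, *n* containing *s*, *np* both):

$$\varphi = \frac{N\,np - n\,Np}{\sqrt{n\,Np\,(N-n)\,(N-Np)}}$$

with φ = 0 when the denominator vanishes. Significance is the one-sided
Fisher exact (upper hypergeometric tail) probability of at least the
observed concentration; one-sided over-representation is the field
convention for fidelity screening and the package default. Fidelity is
presence/absence based with no group-size standardization by default (the
standardized variant is available behind a flag). The fidelity universe is
the full labelled set, each unit contrasted against all remaining relevés,
matching the combined synoptic-table design.

Role thresholds follow the reference protocol exactly, with the stated
boundary semantics (φ and frequency inclusive, p strict): diagnostic
requires φ ≥ 0.25 (associations) or ≥ 0.20 (alliances), p < 0.001 *and*
membership in the preselected 63-species class list; the same fidelity
test without list membership yields differential; constancy ≥ 40 % gives
constant; cover ≥ 25 % in ≥ 5 % of the unit's relevés gives dominant.
Frequencies are rounded to one decimal only on output — role decisions use
unrounded values.

## Geographic stratified resampling

Dense local sampling would otherwise dominate the synoptic statistics, so
classified relevés are thinned on a geographic grid: within every
(cell, unit) stratum at most `per_cell = 3` relevés are kept, drawn
uniformly without replacement. The default cell is 1.25′ longitude ×
0.75′ latitude: arc-minutes, since at ~52° N these are ≈ 1.4 km × 1.4 km
(degrees would be ~85 km cells, uselessly coarse for this purpose). The
grid is anchored at (0°, 0°); no origin convention was published, and an
anchored grid keeps cell assignment a pure function of the coordinates.
Sampling is seeded, sorted before drawing, and therefore invariant to
input order; resampling a sample returns it unchanged.

## Ordination

Covers are transformed entrywise by `x^p` with `p = 0.5` before
ordination, damping dominants. Correspondence analysis is computed by SVD
of the chi-square standardized residuals; scores are standard coordinates
(weighted variance 1), with a deterministic sign convention (positive
weighted skewness) so permuting plots or species permutes but never flips
results.

DCA detrends by segments: axis 1 is the CA axis; each later axis is the
fixed point of reciprocal averaging with, at every iteration, segment-wise
detrending (26 equal-width segments by default) against all previously
extracted axes. Hill's nonlinear rescaling is *not* applied: the segment
count is specified, rescaling was not, and leaving scores in the CA metric
keeps eigenvalues interpretable. Because segment detrending annihilates
constant vectors, no separate centring is needed, and each axis ends with
exactly zero segment means along the axis it was last detrended against.
Numerical choices: iteration tolerance 1e-10 with a 10,000-iteration cap,
initialised from the corresponding CA axis, hence seed-free. When the
iteration does not settle — characteristic of degenerate data such as a
pure single gradient, where detrending removes the arch and the residual
operator's dominant eigenpair is complex — the axis is obtained directly
as the dominant essentially-real eigenvector of the explicitly assembled
iteration operator, which is the limit the iteration seeks. Detrended
eigenvalues are reported in extraction order and need not decrease
monotonically (only the CA eigenvalues are guaranteed non-increasing).

Ellenberg-style indicator values enter as plot-level community-weighted
means, `Σ cᵢvᵢ / Σ cᵢ` over the species with a value for that indicator;
the cover-weighted form is the default (an unweighted mean is available)
because it is the more specific of the two published descriptions.
Indicators are then fitted to the site scores by least squares; the unit
direction vector, squared correlation and a permutation p-value
(≥ 999 permutations recommended, seeded) are reported. These fits are
descriptive projections, not causal estimates. The packaged indicator
table is **synthetic** — plausible values for ephemeral wetland annuals,
shipped only so the CWM and supplementary-fit code paths are exercised;
analyses of real data must supply the published indicator tables.

## The synthetic generator

`generate_releves()` emulates the *structure* the analysis assumes, not
any real database: 14 unit profiles (one per reference unit, plot-count
targets equal to the published per-unit relevé counts) whose core species
are the unit's diagnostic and sociological-group species at high
occurrence probability (mostly 0.8–0.97), with log-uniform covers —
ephemeral vegetation has many low covers and few dominants — whose ranges
are set so the unit's own formal definition fires while foreign
definitions rarely do. A shared background pool (ubiquitous companions
such as *Juncus bufonius* and *Gnaphalium uliginosum*) gives the fidelity
statistics realistic shared species. Coordinates scatter normally
(sd 0.35°) around unit centres inside Poland's bounding box so
stratification strata are non-trivial; areas are uniform on [1, 100] m².
`perturb_releves()` adds record dropout, multiplicative cover jitter and
unlabelled background-only plots — the analogue of stands classifiable
only at higher ranks.

What passing tests on these data do and do not show: they verify the
*mechanics* — definitions fire where constructed to fire, label recovery
(≥ 90 % at defaults; ≈ 95 % observed), fidelity statistics, stratification
and ordination behave as specified. They do not certify performance on
real databases, whose species-richness distributions, spatial clustering
and header errors the generator deliberately does not model.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which every property is meaningfully exercised:
exhaustive fidelity-oracle sweeps over all 2×2 tables with N ≤ 30
(≈ 46,000 tables), 10,000 random relevés for the engine invariants, the
default 14 × 50-plot synthetic data set for label and diagnostic-species
recovery, 200 resampling seeds for the selection-frequency check, and a
50-plot, 30-species deterministic coenocline for DCA.

## Known limitations

* The packaged expert system is a faithful structural reconstruction, not
  a transcription of the published threshold file; results on real data
  will differ from the reference survey in the marginal cases the exact
  thresholds decide.
* Nonlinear rescaling of DCA axes (and hence gradient lengths in SD
  units) is not implemented.
* The published headline numbers that depend on the source database
  (69,562 input relevés; the 1,340/903/541 cascade; DCA axis percentages)
  are not reproducible without that database; the packaged fixtures check
  their internal arithmetic only.
* Cartographic output is limited to per-unit GeoJSON point collections;
  map rendering is out of scope.
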
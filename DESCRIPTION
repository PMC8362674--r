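Package: vegcocktail
Title: Cocktail Expert-System Classification, Fidelity Statistics and
    Detrended Correspondence Analysis for Vegetation-Plot Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Formalized (Cocktail-style) classification of vegetation
    releves. Provides a data model for plot x taxon x layer cover tables
    with Braun-Blanquet cover-scale conversion, taxon merging and
    plot-level filters; a parser and evaluator for expert-system formal
    definitions (AND/OR/NOT over total-cover, single-species-cover and
    sociological species-group conditions) with unequivocal hierarchical
    assignment to class, alliance and association; phi fidelity and
    one-sided Fisher exact significance with synoptic-table construction
    and diagnostic/differential/constant/dominant species roles;
    geographic grid stratified resampling; correspondence analysis with
    detrending by segments and community-weighted mean indicator values
    fitted as supplementary variables; a labelled synthetic releve
    generator emulating ephemeral wetland (Isoeto-Nanojuncetea)
    vegetation; and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
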
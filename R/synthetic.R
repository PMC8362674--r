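#' Shared background species pool
#'
#' Companion species occurring across all ephemeral wetland units —
#' ubiquitous annuals such as *Juncus bufonius* and *Gnaphalium uliginosum*
#' that reach high constancy in every unit — so fidelity statistics face
#' realistic shared species. Probabilities are per-plot occurrence rates;
#' covers are drawn log-uniformly between `lo` and `hi` percent.
#'
#' @return data frame `species`, `prob`, `lo`, `hi`.
#' @export
background_pool <- function() {
  sp <- function(species, prob, lo, hi) {
    data.frame(species = species, prob = prob, lo = lo, hi = hi,
               stringsAsFactors = FALSE)
  }
  rbind(
    sp("Juncus bufonius",                 0.45, 1, 15),
    sp("Gnaphalium uliginosum",           0.40, 1, 10),
    sp("Plantago major subsp. intermedia", 0.35, 1, 10),
    sp("Agrostis stolonifera",            0.30, 1, 15),
    sp("Rorippa palustris",               0.25, 1, 10),
    sp("Persicaria hydropiper",           0.20, 1, 10),
    sp("Polygonum aviculare s. l.",       0.20, 1, 8),
    sp("Bidens tripartitus",              0.15, 1, 8),
    sp("Rumex maritimus",                 0.15, 1, 8),
    sp("Sagina procumbens",               0.15, 1, 8),
    sp("Persicaria lapathifolia s. l.",   0.15, 1, 8),
    sp("Oxybasis rubra",                  0.10, 1, 8),
    sp("Erigeron canadensis",             0.10, 1, 5),
    sp("Mentha arvensis",                 0.10, 1, 5),
    sp("Stellaria media s. l.",           0.10, 1, 5)
  )
}

unit_profile <- function(unit_id, name, alliance, n_target, center, core) {
  structure(list(unit_id = unit_id, name = name, alliance = alliance,
                 n_target = n_target, center = center, scatter = 0.35,
                 area_range = c(1, 100), core = core),
            class = "unit_profile")
}

core_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(species = r[[1]], prob = as.numeric(r[[2]]),
               lo = as.numeric(r[[3]]), hi = as.numeric(r[[4]]),
               marker = isTRUE(r[[5]]), stringsAsFactors = FALSE)
  }))
}

#' Default unit profiles of the synthetic generator
#'
#' One profile per unit of the reference classification (14 units in three
#' alliances). Core species are each unit's diagnostic/sociological-group
#' species at high occurrence probability, with cover ranges chosen so the
#' packaged formal definitions fire for plots of the generating unit and
#' rarely for others; companions are shared at low probability. `marker`
#' flags the unit's signature diagnostic species (class-list members with
#' near-exclusive, high-probability occurrence) used for fidelity-recovery
#' checks. Plot-count targets are the reported per-unit relevé counts.
#'
#' @return list of `unit_profile` objects, one per unit.
#' @export
default_profiles <- function() {
  counts <- load_reported_counts()$units
  n_of <- function(id) counts$releves[counts$unit_id == id]
  list(
    unit_profile(1L, "Polygono-Eleocharitetum ovatae",
                 "Eleocharition soloniensis", n_of(1L), c(16.5, 50.8),
      core_df(
        list("Eleocharis ovata",        0.95, 15, 90, TRUE),
        list("Carex bohemica",          0.85,  5, 50, TRUE),
        list("Lindernia procumbens",    0.60,  2, 25, FALSE),
        list("Elatine hexandra",        0.45,  5, 40, FALSE),
        list("Elatine triandra",        0.35,  2, 25, FALSE),
        list("Elatine hydropiper",      0.35,  2, 25, FALSE),
        list("Eleocharis acicularis",   0.60,  5, 50, FALSE),
        list("Juncus bulbosus",         0.30,  1, 15, FALSE),
        list("Alisma plantago-aquatica", 0.35, 1, 10, FALSE))),
    unit_profile(2L, "Cypero fusci-Limoselletum aquaticae",
                 "Eleocharition soloniensis", n_of(2L), c(15.5, 52.2),
      core_df(
        list("Cyperus fuscus",          0.97, 15, 90, TRUE),
        list("Limosella aquatica",      0.85,  5, 60, FALSE),
        list("Potentilla supina",       0.80,  2, 30, TRUE),
        list("Eleocharis acicularis",   0.40,  2, 20, FALSE))),
    unit_profile(3L, "Cyperetum micheliani",
                 "Eleocharition soloniensis", n_of(3L), c(16.1, 51.7),
      core_df(
        list("Cyperus michelianus",     0.98, 30, 90, TRUE),
        list("Cyperus fuscus",          0.30,  2, 20, FALSE),
        list("Limosella aquatica",      0.25,  2, 20, FALSE))),
    unit_profile(4L, "Community with Coleanthus subtilis",
                 "Eleocharition soloniensis", n_of(4L), c(16.9, 51.2),
      core_df(
        list("Coleanthus subtilis",     0.97, 10, 80, TRUE),
        list("Veronica peregrina",      0.85,  2, 30, TRUE),
        list("Myosurus minimus",        0.55,  2, 20, FALSE),
        list("Riccia cavernosa",        0.60,  2, 25, FALSE),
        list("Limosella aquatica",      0.50,  2, 25, FALSE),
        list("Ranunculus trichophyllus", 0.30, 1, 10, FALSE),
        list("Callitriche palustris s. l.", 0.35, 1, 10, FALSE))),
    unit_profile(5L, "Veronico anagalloidis-Lythretum hyssopifoliae",
                 "Verbenion supinae", n_of(5L), c(18.0, 52.5),
      core_df(
        list("Juncus ranarius",         0.95, 10, 80, TRUE),
        list("Lythrum hyssopifolia",    0.35,  2, 20, FALSE),
        list("Veronica anagalloides",   0.50,  2, 20, FALSE),
        list("Juncus compressus",       0.40,  1, 10, FALSE),
        list("Atriplex prostrata",      0.35,  1, 10, FALSE),
        list("Argentina anserina",      0.30,  1, 10, FALSE),
        list("Carex secalina",          0.25,  2, 20, FALSE),
        list("Bolboschoenus maritimus agg.", 0.25, 2, 25, FALSE))),
    unit_profile(6L, "Cyperetum flavescentis",
                 "Verbenion supinae", n_of(6L), c(22.5, 50.5),
      core_df(
        list("Cyperus flavescens",      0.97, 30, 90, TRUE),
        list("Sagina nodosa",           0.70,  2, 20, TRUE),
        list("Ranunculus flammula",     0.50,  1, 10, FALSE),
        list("Juncus articulatus",      0.50,  1, 15, FALSE),
        list("Calliergonella cuspidata", 0.45, 2, 20, FALSE),
        list("Triglochin palustris",    0.30,  1, 8, FALSE))),
    unit_profile(7L, "Pulicario vulgaris-Menthetum pulegii",
                 "Verbenion supinae", n_of(7L), c(15.8, 52.0),
      core_df(
        list("Pulicaria vulgaris",      0.95, 10, 80, TRUE),
        list("Mentha pulegium",         0.50,  5, 40, FALSE),
        list("Inula britannica",        0.35,  1, 10, FALSE),
        list("Xanthium orientale subsp. italicum", 0.30, 1, 10, FALSE),
        list("Lysimachia nummularia",   0.30,  1, 15, FALSE),
        list("Poa pratensis",           0.25,  1, 8, FALSE))),
    unit_profile(8L, "Eleocharito-Schoenoplectetum supini",
                 "Verbenion supinae", n_of(8L), c(22.8, 51.0),
      core_df(
        list("Elatine alsinastrum",     0.95, 10, 80, TRUE),
        list("Schoenoplectus supinus",  0.85,  5, 50, TRUE),
        list("Alisma lanceolatum",      0.80,  2, 30, FALSE),
        list("Lythrum hyssopifolia",    0.45,  2, 20, FALSE),
        list("Limosella aquatica",      0.30,  1, 10, FALSE),
        list("Persicaria amphibia",     0.30,  1, 8, FALSE))),
    unit_profile(9L, "Stellario uliginosae-Isolepidetum setaceae",
                 "Radiolion linoidis", n_of(9L), c(15.2, 51.8),
      core_df(
        list("Isolepis setacea",        0.95, 10, 80, TRUE),
        list("Juncus tenageia",         0.85,  2, 30, FALSE),
        list("Stellaria alsine",        0.80,  2, 25, FALSE),
        list("Radiola linoides",        0.30,  1, 10, FALSE),
        list("Juncus articulatus",      0.50,  1, 15, FALSE),
        list("Juncus effusus",          0.30,  1, 10, FALSE),
        list("Leontodon saxatilis",     0.25,  1, 5, FALSE))),
    unit_profile(10L, "Centunculo minimi-Anthoceretum punctati",
                 "Radiolion linoidis", n_of(10L), c(21.5, 51.5),
      core_df(
        list("Anagallis minima",        0.95,  5, 50, TRUE),
        list("Anthoceros punctatus s. l.", 0.85, 5, 40, FALSE),
        list("Radiola linoides",        0.70,  2, 30, FALSE),
        list("Juncus capitatus",        0.70,  2, 25, TRUE),
        list("Phaeoceros laevis",       0.40,  2, 15, FALSE),
        list("Rumex acetosella",        0.40,  1, 10, FALSE),
        list("Spergula arvensis",       0.35,  1, 10, FALSE),
        list("Equisetum arvense",       0.30,  1, 8, FALSE),
        list("Hypericum humifusum",     0.25,  1, 8, FALSE),
        list("Gypsophila muralis",      0.20,  1, 8, FALSE))),
    unit_profile(11L, "Hyperico humifusi-Spergularietum rubrae",
                 "Radiolion linoidis", n_of(11L), c(22.0, 50.8),
      core_df(
        list("Spergularia rubra",       0.95,  5, 50, TRUE),
        list("Gypsophila muralis",      0.90,  5, 40, TRUE),
        list("Hypericum humifusum",     0.70,  2, 30, FALSE),
        list("Laphangium luteoalbum",   0.65,  2, 20, TRUE),
        list("Anagallis minima",        0.25,  1, 8, FALSE),
        list("Scleranthus annuus",      0.40,  1, 10, FALSE),
        list("Rumex acetosella",        0.40,  1, 10, FALSE),
        list("Spergula arvensis",       0.35,  1, 10, FALSE),
        list("Setaria pumila",          0.25,  1, 8, FALSE))),
    unit_profile(12L, "Panico-Illecebretum verticillati",
                 "Radiolion linoidis", n_of(12L), c(21.8, 51.2),
      core_df(
        list("Illecebrum verticillatum", 0.95, 10, 80, TRUE),
        list("Spergularia rubra",       0.50,  2, 20, FALSE),
        list("Hypericum humifusum",     0.45,  2, 15, FALSE),
        list("Radiola linoides",        0.40,  2, 15, FALSE),
        list("Teesdalia nudicaulis",    0.40,  1, 10, FALSE),
        list("Arnoseris minima",        0.30,  1, 8, FALSE),
        list("Spergula arvensis",       0.50,  1, 12, FALSE),
        list("Scleranthus annuus",      0.40,  1, 10, FALSE),
        list("Rumex acetosella",        0.45,  1, 12, FALSE),
        list("Digitaria ischaemum",     0.25,  1, 8, FALSE))),
    unit_profile(13L, "Cerastio dubii-Ranunculetum sardoi",
                 "Radiolion linoidis", n_of(13L), c(17.5, 51.5),
      core_df(
        list("Ranunculus sardous",      0.95, 10, 70, TRUE),
        list("Myosurus minimus",        0.90,  5, 50, FALSE),
        list("Bryum ruderale",          0.70,  2, 20, FALSE),
        list("Cerastium dubium",        0.35,  2, 15, FALSE),
        list("Capsella bursa-pastoris", 0.40,  1, 8, FALSE),
        list("Bryum dichotomum",        0.30,  1, 8, FALSE))),
    unit_profile(14L, "Community with Montia arvensis",
                 "Radiolion linoidis", n_of(14L), c(15.2, 52.1),
      core_df(
        list("Montia arvensis",         0.97, 10, 70, TRUE),
        list("Myosurus minimus",        0.60,  2, 25, FALSE),
        list("Riccia sorocarpa",        0.60,  2, 20, FALSE),
        list("Dicranella staphylina",   0.40,  1, 10, FALSE),
        list("Holcus lanatus",          0.35,  1, 10, FALSE),
        list("Ranunculus repens",       0.30,  1, 8, FALSE),
        list("Veronica arvensis",       0.30,  1, 8, FALSE)))
  )
}

#' Signature (marker) species of each default unit profile
#' @param profiles list of profiles ([default_profiles()]).
#' @return named list: unit name -> character vector of marker species.
#' @export
unit_markers <- function(profiles = default_profiles()) {
  out <- lapply(profiles, function(p) p$core$species[p$core$marker])
  names(out) <- vapply(profiles, `[[`, character(1), "name")
  out
}

r_log_uniform <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Generate a labelled synthetic releve data set
#'
#' For every plot of every unit: core species occur with their profile
#' probabilities and log-uniform covers, background species with the shared
#' pool rates; coordinates are Gaussian around the unit centre (`scatter`
#' degrees sd), areas uniform on `[1, 100]` m2, dates uniform over summer
#' field seasons. Output is bit-identical for equal configuration and seed.
#'
#' @param profiles list of unit profiles ([default_profiles()]).
#' @param n_per_unit plots per unit; `NULL` uses each profile's
#'   `n_target`. A single number or a vector along `profiles`.
#' @param seed RNG seed.
#' @param background background-species pool data frame
#'   ([background_pool()]).
#' @return list of class `synthetic_releves`: `table` (a `releve_table`),
#'   `labels` (named unit per plot), `profiles`, `seed`.
#' @export
generate_releves <- function(profiles = default_profiles(),
                             n_per_unit = NULL, seed = 1,
                             background = background_pool()) {
  stopifnot(length(profiles) >= 1)
  n <- if (is.null(n_per_unit)) {
    vapply(profiles, `[[`, numeric(1), "n_target")
  } else {
    rep_len(n_per_unit, length(profiles))
  }
  stopifnot(all(n >= 0))
  with_seed(seed, {
    recs <- list()
    hdrs <- list()
    labels <- character(0)
    for (k in seq_along(profiles)) {
      pr <- profiles[[k]]
      if (n[k] == 0) next
      ids <- sprintf("u%02d_%04d", pr$unit_id, seq_len(n[k]))
      pool <- rbind(pr$core[c("species", "prob", "lo", "hi")],
                    background[!normalize_name(background$species) %in%
                                 normalize_name(pr$core$species),
                               c("species", "prob", "lo", "hi")])
      for (i in seq_len(n[k])) {
        occ <- stats::runif(nrow(pool)) < pool$prob
        if (any(occ)) {
          cov <- r_log_uniform(sum(occ), pool$lo[occ], pool$hi[occ]) / 100
          recs[[length(recs) + 1L]] <- data.frame(
            plot_id = ids[i], taxon = pool$species[occ], layer = "herb",
            cover = pmin(cov, 1), stringsAsFactors = FALSE)
        }
      }
      hdrs[[length(hdrs) + 1L]] <- data.frame(
        plot_id = ids,
        lon = stats::rnorm(n[k], pr$center[1], pr$scatter),
        lat = stats::rnorm(n[k], pr$center[2], pr$scatter),
        area_m2 = stats::runif(n[k], pr$area_range[1], pr$area_range[2]),
        date = sprintf("%d-%02d-%02d", sample(2010:2019, n[k], TRUE),
                       sample(6:9, n[k], TRUE), sample(1:28, n[k], TRUE)),
        stringsAsFactors = FALSE)
      labels <- c(labels, stats::setNames(rep(pr$name, n[k]), ids))
    }
    table <- releve_table(
      if (length(recs)) do.call(rbind, recs) else NULL,
      if (length(hdrs)) do.call(rbind, hdrs) else
        data.frame(plot_id = character(), stringsAsFactors = FALSE))
    structure(list(table = table, labels = labels, profiles = profiles,
                   seed = seed),
              class = "synthetic_releves")
  })
}

#' @export
print.synthetic_releves <- function(x, ...) {
  cat("synthetic_releves:", n_plots(x$table), "plots,",
      length(unique(x$labels)), "units, seed", x$seed, "\n")
  invisible(x)
}

#' Perturb a synthetic data set
#'
#' Models the noise real surveys carry: `dropout` deletes each record with
#' that probability; `jitter` multiplies covers by `exp(jitter * z)`,
#' `z ~ N(0,1)` (clamped to `(0, 1]`); `background_frac` injects that
#' fraction of additional plots drawn from the background pool only, with
#' `NA` labels — stands expected to classify at class/alliance level or not
#' at all.
#'
#' @param dataset a [generate_releves()] result.
#' @param dropout record-deletion rate in `[0, 1]`.
#' @param jitter multiplicative log-normal cover noise sd (0 = none).
#' @param background_frac fraction of injected background-only plots.
#' @param seed RNG seed.
#' @return a `synthetic_releves` object.
#' @export
perturb_releves <- function(dataset, dropout = 0, jitter = 0,
                            background_frac = 0, seed = 1) {
  stopifnot(inherits(dataset, "synthetic_releves"),
            dropout >= 0, dropout <= 1, jitter >= 0,
            background_frac >= 0, background_frac <= 1)
  if (dropout == 0 && jitter == 0 && background_frac == 0) return(dataset)
  with_seed(seed, {
    rec <- dataset$table$records
    hdr <- dataset$table$header
    labels <- dataset$labels
    if (dropout > 0 && nrow(rec)) {
      rec <- rec[stats::runif(nrow(rec)) >= dropout, , drop = FALSE]
    }
    if (jitter > 0 && nrow(rec)) {
      rec$cover <- pmin(rec$cover * exp(jitter * stats::rnorm(nrow(rec))), 1)
      rec$cover <- pmax(rec$cover, 1e-4)
    }
    n_extra <- round(background_frac * nrow(hdr))
    if (n_extra > 0) {
      pool <- background_pool()
      ids <- sprintf("bg_%04d", seq_len(n_extra))
      for (i in seq_len(n_extra)) {
        occ <- stats::runif(nrow(pool)) < pmax(pool$prob, 0.3)
        if (!any(occ)) occ[sample(nrow(pool), 2)] <- TRUE
        rec <- rbind(rec, data.frame(
          plot_id = ids[i], taxon = pool$species[occ], layer = "herb",
          cover = pmin(r_log_uniform(sum(occ), pool$lo[occ],
                                     pool$hi[occ]) / 100, 1),
          stringsAsFactors = FALSE))
      }
      hdr <- rbind(hdr, data.frame(
        plot_id = ids,
        lon = stats::runif(n_extra, 14.5, 23.5),
        lat = stats::runif(n_extra, 49.5, 54.5),
        area_m2 = stats::runif(n_extra, 1, 100),
        date = rep("2015-07-15", n_extra), stringsAsFactors = FALSE))
      labels <- c(labels, stats::setNames(rep(NA_character_, n_extra), ids))
    }
    structure(list(table = releve_table(rec, hdr), labels = labels,
                   profiles = dataset$profiles, seed = seed),
              class = "synthetic_releves")
  })
}
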
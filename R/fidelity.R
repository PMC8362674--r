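#' Phi fidelity coefficient
#'
#' Presence/absence fidelity of a species to a vegetation unit, computed
#' from the 2x2 table of the labelled data set: `N` relevés in total, `Np`
#' in the target unit, `n` containing the species, `np` in the unit and
#' containing the species.
#'
#' `phi = (N*np - n*Np) / sqrt(n * Np * (N - n) * (N - Np))`
#'
#' By convention phi is 0 whenever the denominator vanishes (species
#' everywhere or nowhere, unit empty or universal). No cover weighting and
#' no group-size standardization are applied; `standardize` rescales the
#' unit to an equal share `Np' = N/2` of the data set (Tichý-style
#' standardized phi) when requested.
#'
#' All arguments are vectorized.
#'
#' @param N total relevé count.
#' @param Np relevés in the target unit.
#' @param n relevés containing the species.
#' @param np relevés of the unit containing the species.
#' @param standardize equalize unit sizes before computing phi?
#' @return phi values in `[-1, 1]`.
#' @export
phi_fidelity <- function(N, Np, n, np, standardize = FALSE) {
  N <- as.numeric(N); Np <- as.numeric(Np)
  n <- as.numeric(n); np <- as.numeric(np)
  check_fidelity_input(N, Np, n, np)
  if (standardize) {
    # rescale unit and complement to equal weight; counts become rates
    inside <- ifelse(Np > 0, np / Np, 0)
    outside <- ifelse(N - Np > 0, (n - np) / (N - Np), 0)
    Np <- N / 2
    np <- inside * Np
    n <- np + outside * (N - Np)
  }
  den2 <- n * Np * (N - n) * (N - Np)
  num <- N * np - n * Np
  ifelse(den2 > 0, num / sqrt(den2), 0)
}

check_fidelity_input <- function(N, Np, n, np) {
  ok <- np >= 0 & np <= pmin(n, Np) & Np <= N & n <= N &
    np >= pmax(0, n + Np - N)
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop("inconsistent 2x2 fidelity counts: N=", N[min(i, length(N))],
         " Np=", Np[min(i, length(Np))], " n=", n[min(i, length(n))],
         " np=", np[min(i, length(np))])
  }
  invisible(TRUE)
}

#' One-sided Fisher exact test for over-representation
#'
#' Upper hypergeometric tail `P(X >= np)` for `X ~ Hypergeom(N, Np, n)`
#' (population `N`, `Np` unit members, `n` draws = species occurrences):
#' the probability of observing at least the attained concentration of the
#' species in the unit by chance.
#'
#' Vectorized like [phi_fidelity()].
#'
#' @inheritParams phi_fidelity
#' @return p-values in `(0, 1]`.
#' @export
fisher_one_sided <- function(N, Np, n, np) {
  N <- as.numeric(N); Np <- as.numeric(Np)
  n <- as.numeric(n); np <- as.numeric(np)
  check_fidelity_input(N, Np, n, np)
  stats::phyper(np - 1, Np, N - Np, n, lower.tail = FALSE)
}

#' Build a synoptic table
#'
#' For every unit of the labelling and every species of the labelled plots,
#' computes percentage frequency (constancy) `100 * np / Np`, the phi
#' fidelity and the one-sided Fisher p, all over the pooled labelled
#' universe (each unit contrasted against all remaining labelled relevés).
#'
#' @param table a `releve_table`.
#' @param labels named character vector mapping plot ids to unit names;
#'   every named plot must exist in `table`.
#' @param standardize passed to [phi_fidelity()].
#' @return data frame of class `synoptic_table` with columns `unit`,
#'   `species`, `N`, `Np`, `n`, `np`, `freq`, `phi`, `p`.
#' @export
build_synoptic <- function(table, labels, standardize = FALSE) {
  stopifnot(inherits(table, "releve_table"), is.character(labels),
            !is.null(names(labels)))
  labels <- labels[!is.na(labels)]
  missing <- setdiff(names(labels), plot_ids(table))
  if (length(missing)) {
    stop("labelled plot(s) not in table: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  if (!length(labels)) stop("no labelled plots")
  units <- sort(unique(labels))
  plots <- names(labels)
  rec <- table$records[table$records$plot_id %in% plots, , drop = FALSE]
  rec <- rec[rec$cover > 0, , drop = FALSE]
  rec$ntaxon <- normalize_name(rec$taxon)
  # presence of each (plot, species), one row each
  pres <- unique(rec[c("plot_id", "ntaxon")])
  display <- rec$taxon[!duplicated(rec$ntaxon)]
  names(display) <- rec$ntaxon[!duplicated(rec$ntaxon)]
  species <- sort(unique(pres$ntaxon))
  N <- length(plots)
  n_all <- table(factor(pres$ntaxon, levels = species))
  out <- do.call(rbind, lapply(units, function(u) {
    uplots <- plots[labels == u]
    Np <- length(uplots)
    np <- table(factor(pres$ntaxon[pres$plot_id %in% uplots],
                       levels = species))
    data.frame(unit = u, species = unname(display[species]),
               N = N, Np = Np, n = as.integer(n_all), np = as.integer(np),
               freq = 100 * as.integer(np) / Np,
               phi = phi_fidelity(N, Np, as.integer(n_all), as.integer(np),
                                  standardize = standardize),
               p = fisher_one_sided(N, Np, as.integer(n_all),
                                    as.integer(np)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("synoptic_table", "data.frame")
  out
}

#' Role thresholds for synoptic species roles
#'
#' Defaults follow the reference protocol: diagnostic/differential at
#' phi >= 0.20 for alliances and phi >= 0.25 for associations, with Fisher
#' p < 0.001 (strict); diagnostic additionally requires membership in the
#' preselected class species list, otherwise the species is differential.
#' Constant species have frequency >= 40 %; dominant species reach >= 25 %
#' cover in >= 5 % of the unit's relevés. Boundary semantics are exactly as
#' stated (phi and frequency inclusive, p strict).
#'
#' @param phi_alliance,phi_association fidelity thresholds.
#' @param p_max Fisher significance bound (strict `<`).
#' @param constancy_min constancy threshold, percent.
#' @param dominance_cover cover threshold for dominance, percent.
#' @param dominance_freq share of relevés that must reach it, percent.
#' @param class_species species eligible for the diagnostic role.
#' @return a list of class `role_thresholds`.
#' @export
role_thresholds <- function(phi_alliance = 0.20, phi_association = 0.25,
                            p_max = 0.001, constancy_min = 40,
                            dominance_cover = 25, dominance_freq = 5,
                            class_species = load_class_species()) {
  structure(list(phi_alliance = phi_alliance,
                 phi_association = phi_association, p_max = p_max,
                 constancy_min = constancy_min,
                 dominance_cover = dominance_cover,
                 dominance_freq = dominance_freq,
                 class_species = class_species,
                 norm_class_species = normalize_name(class_species)),
            class = "role_thresholds")
}

#' Assign species roles in a synoptic table
#'
#' Adds the four role flags:
#' * `diagnostic`: phi >= rank threshold, p < `p_max`, and the species is
#'   in the preselected class species list;
#' * `differential`: same fidelity test but not in the list;
#' * `constant`: frequency >= `constancy_min`;
#' * `dominant`: cover >= `dominance_cover` in at least `dominance_freq` %
#'   of the unit's relevés.
#'
#' Role decisions use unrounded values.
#'
#' @param syn a [build_synoptic()] result.
#' @param table the `releve_table` the synoptic table was built from
#'   (needed for the dominance criterion).
#' @param labels the plot -> unit labelling used.
#' @param ranks named character vector mapping each unit to `"alliance"` or
#'   `"association"` (chooses the phi threshold).
#' @param thresholds a [role_thresholds()].
#' @return the synoptic table with logical columns `diagnostic`,
#'   `differential`, `constant`, `dominant` and a `roles` summary string.
#' @export
species_roles <- function(syn, table, labels, ranks,
                          thresholds = role_thresholds()) {
  stopifnot(inherits(syn, "synoptic_table"),
            inherits(thresholds, "role_thresholds"))
  units <- unique(syn$unit)
  if (!all(units %in% names(ranks))) {
    stop("ranks must name every unit of the synoptic table")
  }
  if (!all(ranks[units] %in% c("alliance", "association"))) {
    stop("ranks must be 'alliance' or 'association'")
  }
  phi_thr <- ifelse(ranks[syn$unit] == "alliance",
                    thresholds$phi_alliance, thresholds$phi_association)
  fid_ok <- syn$phi >= phi_thr & syn$p < thresholds$p_max
  in_list <- normalize_name(syn$species) %in% thresholds$norm_class_species
  syn$diagnostic <- fid_ok & in_list
  syn$differential <- fid_ok & !in_list
  syn$constant <- syn$freq >= thresholds$constancy_min
  # dominance: share of the unit's releves where the species reaches the
  # cover threshold (layers pooled)
  labels <- labels[!is.na(labels)]
  covs <- plot_covers(subset_releves(table, names(labels)))
  dom_share <- mapply(function(u, sp) {
    uplots <- names(labels)[labels == u]
    nsp <- normalize_name(sp)
    hit <- vapply(covs[uplots], function(cv) {
      v <- cv[nsp]
      !is.na(v) && 100 * v >= thresholds$dominance_cover
    }, logical(1))
    100 * mean(hit)
  }, syn$unit, syn$species)
  syn$dominant <- unname(dom_share) >= thresholds$dominance_freq
  syn$roles <- apply(syn[c("diagnostic", "differential", "constant",
                           "dominant")], 1L, function(fl) {
    paste(c("diagnostic", "differential", "constant",
            "dominant")[as.logical(fl)], collapse = ",")
  })
  syn
}

#' Write a synoptic table to CSV
#'
#' Long CSV ordered by unit block and descending phi within unit, with
#' frequencies rounded to one decimal for display (role flags were computed
#' on unrounded values).
#'
#' @param syn a synoptic table ([build_synoptic()] / [species_roles()]).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_synoptic <- function(syn, path) {
  stopifnot(inherits(syn, "synoptic_table"))
  out <- as.data.frame(syn)
  out <- out[order(out$unit, -out$phi, out$species), , drop = FALSE]
  out$freq <- round(out$freq, 1)
  out$phi <- round(out$phi, 3)
  out$p <- signif(out$p, 3)
  write_delim_auto(out, path)
  invisible(path)
}
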
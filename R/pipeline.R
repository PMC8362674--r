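#' Pipeline configuration
#'
#' Collects every knob of the end-to-end workflow. Inputs may be given as
#' file paths (`species`, `headers`) or as an in-memory `releve_table`
#' (`table`); `hierarchy`/`groups` default to the packaged reconstructed
#' expert system.
#'
#' @param species,headers input file paths (see [read_releves()]).
#' @param table alternatively, a ready `releve_table`.
#' @param scale cover scale for file input.
#' @param merge_map optional taxon merge map (named vector or YAML path).
#' @param min_area,max_area,require_coords,cultivated plot filters
#'   ([filter_releves()]).
#' @param groups species-group registry.
#' @param hierarchy syntaxon hierarchy (object or YAML path).
#' @param grid grid specification for stratified resampling.
#' @param per_cell plots kept per (cell, unit) stratum.
#' @param thresholds role thresholds ([role_thresholds()]).
#' @param eiv optional indicator-value table (data frame or CSV path) for
#'   the ordination stage.
#' @param dca_p,dca_segments,dca_axes DCA settings (cover-transform
#'   exponent, detrending segments, axes).
#' @param permutations permutations for supplementary-variable fits.
#' @param seed seed controlling stratification and permutation tests.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(species = NULL, headers = NULL, table = NULL,
                            scale = bb_scale(), merge_map = NULL,
                            min_area = 1, max_area = 100,
                            require_coords = TRUE, cultivated = character(),
                            groups = load_packaged_groups(),
                            hierarchy = load_packaged_hierarchy(),
                            grid = grid_spec(), per_cell = 3,
                            thresholds = role_thresholds(), eiv = NULL,
                            dca_p = 0.5, dca_segments = 26, dca_axes = 4,
                            permutations = 199, seed = 1) {
  if (is.null(table) && is.null(species)) {
    stop("either 'table' or 'species' must be given")
  }
  if (is.character(hierarchy)) hierarchy <- read_hierarchy(hierarchy, groups)
  if (is.character(eiv)) eiv <- read_eiv(eiv)
  structure(list(species = species, headers = headers, table = table,
                 scale = scale, merge_map = merge_map, min_area = min_area,
                 max_area = max_area, require_coords = require_coords,
                 cultivated = cultivated, groups = groups,
                 hierarchy = hierarchy, grid = grid, per_cell = per_cell,
                 thresholds = thresholds, eiv = eiv, dca_p = dca_p,
                 dca_segments = dca_segments, dca_axes = dca_axes,
                 permutations = permutations, seed = seed),
            class = "pipeline_config")
}

#' Run the full classification workflow
#'
#' Stages, in survey order: read -> merge taxa -> plot filters ->
#' expert-system classification -> geographic stratified resampling of the
#' classified relevés (per finest assigned unit) -> per-level counts ->
#' synoptic tables with species roles (association level and alliance
#' level) -> DCA of the association-assigned relevés with
#' community-weighted mean indicator values fitted as supplementary
#' variables (when an indicator table is configured) -> optional exports.
#'
#' Any stage failure aborts with the stage name. Two runs with the same
#' configuration and seed produce byte-identical outputs (no timestamps).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes
#'   `results.tsv`, `counts.json`, `synoptic_associations.csv`,
#'   `synoptic_alliances.csv`, `dca_sites.csv`, `dca_species.csv`,
#'   `dca_eigenvalues.csv`, `supplementary_fit.csv`, per-unit GeoJSON and
#'   `report.md` plus a `manifest.csv` of MD5 checksums.
#' @return list of class `pipeline_result` with elements `table`
#'   (stratified), `classification`, `labels`, `counts`, `synoptic_assoc`,
#'   `synoptic_alliance`, `dca`, `supplementary`, `report` (character
#'   vector of report lines), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- character(0)
  say <- function(...) report <<- c(report, paste0(...))
  say("# Classification pipeline report")
  say("")
  say("seed: ", config$seed)

  table <- stage("read", {
    if (!is.null(config$table)) config$table
    else read_releves(config$species, config$headers, config$scale)
  })
  say("plots read: ", n_plots(table))
  if (!is.null(config$merge_map)) {
    table <- stage("merge_taxa", merge_taxa(table, config$merge_map))
  }
  table <- stage("filter", filter_releves(
    table, config$min_area, config$max_area, config$require_coords,
    config$cultivated))
  fl <- attr(table, "filter_log")
  say("plots kept after filters: ", fl$plots_kept, " (removed ",
      fl$plots_removed_no_coords, " without coordinates, ",
      fl$plots_removed_area, " by area; ",
      fl$records_removed_cultivated, " cultivated records dropped)")

  cls <- stage("classify", classify_table(table, config$hierarchy))
  s <- attr(cls, "summary")
  say("classified: ", s$levels[["association_level"]],
      " at association level, ", s$levels[["alliance_only"]],
      " at alliance level only, ", s$levels[["class_only"]],
      " at class level only, ", s$levels[["unassigned"]], " unassigned")

  # finest assigned unit per plot drives the stratification
  finest <- ifelse(!is.na(cls$association), cls$association,
                   ifelse(!is.na(cls$alliance), cls$alliance, cls$class))
  names(finest) <- cls$plot_id
  finest <- finest[!is.na(finest)]
  strat <- stage("stratify", stratified_sample(
    subset_releves(table, names(finest)), finest, config$grid,
    config$per_cell, seed = config$seed))
  labels <- attr(strat, "labels")
  say("after geographic stratification (", config$per_cell,
      " per cell and unit): ", n_plots(strat), " releves")

  cls_strat <- cls[cls$plot_id %in% plot_ids(strat), , drop = FALSE]
  class(cls_strat) <- class(cls)
  counts <- classification_summary(cls_strat, config$hierarchy)
  say("")
  say("## Releves per syntaxon (stratified set)")
  say("")
  pn <- counts$per_node
  for (i in seq_len(nrow(pn))) {
    say("- ", pn$name[i], " (", pn$rank[i], "): ", pn$n[i])
  }

  # synoptic tables: association-level units, then alliances
  assoc_labels <- stats::setNames(cls_strat$association, cls_strat$plot_id)
  assoc_labels <- assoc_labels[!is.na(assoc_labels)]
  syn_assoc <- NULL
  if (length(assoc_labels)) {
    syn_assoc <- stage("synoptic_associations", {
      syn <- build_synoptic(strat, assoc_labels)
      ranks <- stats::setNames(rep("association",
                                   length(unique(assoc_labels))),
                               unique(assoc_labels))
      species_roles(syn, strat, assoc_labels, ranks, config$thresholds)
    })
  }
  alli_labels <- stats::setNames(cls_strat$alliance, cls_strat$plot_id)
  alli_labels <- alli_labels[!is.na(alli_labels)]
  syn_alli <- NULL
  if (length(alli_labels)) {
    syn_alli <- stage("synoptic_alliances", {
      syn <- build_synoptic(strat, alli_labels)
      ranks <- stats::setNames(rep("alliance", length(unique(alli_labels))),
                               unique(alli_labels))
      species_roles(syn, strat, alli_labels, ranks, config$thresholds)
    })
  }

  # ordination of the association-assigned releves
  dres <- NULL
  sup <- NULL
  if (length(assoc_labels) >= 10) {
    dres <- stage("dca", {
      m <- community_matrix(subset_releves(strat, names(assoc_labels)))
      dca(transform_cover(m, config$dca_p), n_axes = config$dca_axes,
          n_segments = config$dca_segments)
    })
    say("")
    say("## DCA (association-assigned releves, n = ",
        length(assoc_labels), ")")
    say("")
    say("eigenvalues: ",
        paste(signif(dres$eigenvalues, 4), collapse = ", "))
    if (!is.null(config$eiv)) {
      sup <- stage("supplementary_fit", {
        cwm <- cwm_eiv(subset_releves(strat, names(assoc_labels)),
                       config$eiv)
        ok <- rownames(dres$site_scores)
        fit_supplementary(dres, cwm[match(ok, cwm$plot_id), , drop = FALSE],
                          permutations = config$permutations,
                          seed = config$seed)
      })
      for (i in seq_len(nrow(sup))) {
        say("- ", sup$indicator[i], ": r2 = ", signif(sup$r2[i], 3),
            ", p = ", signif(sup$p[i], 3))
      }
    }
  }

  out <- structure(list(table = strat, classification = cls_strat,
                        labels = labels, counts = counts,
                        synoptic_assoc = syn_assoc,
                        synoptic_alliance = syn_alli, dca = dres,
                        supplementary = sup, report = report,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cls <- as.data.frame(result$classification)
  write_delim_auto(cls, file.path(out_dir, "results.tsv"))
  jsonlite::write_json(
    list(per_node = result$counts$per_node,
         levels = as.list(result$counts$levels)),
    file.path(out_dir, "counts.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (!is.null(result$synoptic_assoc)) {
    write_synoptic(result$synoptic_assoc,
                   file.path(out_dir, "synoptic_associations.csv"))
  }
  if (!is.null(result$synoptic_alliance)) {
    write_synoptic(result$synoptic_alliance,
                   file.path(out_dir, "synoptic_alliances.csv"))
  }
  if (!is.null(result$dca)) {
    d <- result$dca
    write_delim_auto(data.frame(plot_id = rownames(d$site_scores),
                                d$site_scores, check.names = FALSE),
                     file.path(out_dir, "dca_sites.csv"))
    write_delim_auto(data.frame(species = rownames(d$species_scores),
                                d$species_scores, check.names = FALSE),
                     file.path(out_dir, "dca_species.csv"))
    write_delim_auto(data.frame(axis = seq_along(d$eigenvalues),
                                eigenvalue = d$eigenvalues),
                     file.path(out_dir, "dca_eigenvalues.csv"))
  }
  if (!is.null(result$supplementary)) {
    write_delim_auto(as.data.frame(result$supplementary),
                     file.path(out_dir, "supplementary_fit.csv"))
  }
  export_unit_geojson(result$table, result$labels, out_dir)
  writeLines(result$report, file.path(out_dir, "report.md"))
  files <- sort(setdiff(list.files(out_dir), "manifest.csv"))
  md5 <- tools::md5sum(file.path(out_dir, files))
  write_delim_auto(data.frame(file = files, md5 = unname(md5)),
                   file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}
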
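#' Releve tables
#'
#' A `releve_table` bundles the species records of a set of vegetation plots
#' (long format: `plot_id`, `taxon`, `layer`, `cover` as a fraction in
#' `(0, 1]`) with a per-plot header (`plot_id`, `lon`, `lat`, `area_m2`,
#' `date`). At most one record may exist per `(plot, taxon, layer)`; header
#' plot ids are unique and cover every plot of the records.
#'
#' @param records data frame with columns `plot_id`, `taxon`, `layer`,
#'   `cover` (fractions in `[0, 1]`).
#' @param header optional data frame with `plot_id` and any of `lon`, `lat`,
#'   `area_m2`, `date`; missing columns / plots are filled with `NA`.
#' @return an object of class `releve_table`.
#' @export
releve_table <- function(records = NULL, header = NULL) {
  if (is.null(records)) {
    records <- data.frame(plot_id = character(), taxon = character(),
                          layer = character(), cover = numeric(),
                          stringsAsFactors = FALSE)
  }
  req <- c("plot_id", "taxon", "layer", "cover")
  if (!all(req %in% names(records))) {
    stop("records need columns: ", paste(req, collapse = ", "))
  }
  records <- records[req]
  records$plot_id <- as.character(records$plot_id)
  records$taxon <- as.character(records$taxon)
  records$layer <- as.character(records$layer)
  records$cover <- as.numeric(records$cover)
  if (nrow(records) && (any(is.na(records$cover)) ||
                        any(records$cover < 0 | records$cover > 1))) {
    stop("record covers must be fractions in [0, 1]")
  }
  key <- paste(records$plot_id, normalize_name(records$taxon), records$layer,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop("duplicate (plot, taxon, layer) record(s), e.g. plot '",
         d$plot_id[1], "', taxon '", d$taxon[1], "', layer '", d$layer[1], "'")
  }
  plots <- unique(records$plot_id)
  hcols <- c("plot_id", "lon", "lat", "area_m2", "date")
  if (is.null(header)) {
    header <- data.frame(plot_id = plots, stringsAsFactors = FALSE)
  }
  header <- as.data.frame(header, stringsAsFactors = FALSE)
  if (!"plot_id" %in% names(header)) stop("header needs a plot_id column")
  header$plot_id <- as.character(header$plot_id)
  if (anyDuplicated(header$plot_id)) stop("duplicate plot_id in header")
  for (cn in setdiff(hcols, names(header))) {
    header[[cn]] <- rep(if (cn == "date") NA_character_ else NA_real_,
                        nrow(header))
  }
  header <- header[hcols]
  header$lon <- as.numeric(header$lon)
  header$lat <- as.numeric(header$lat)
  header$area_m2 <- as.numeric(header$area_m2)
  header$date <- as.character(header$date)
  missing_plots <- setdiff(plots, header$plot_id)
  if (length(missing_plots)) {
    add <- data.frame(plot_id = missing_plots, lon = NA_real_, lat = NA_real_,
                      area_m2 = NA_real_, date = NA_character_,
                      stringsAsFactors = FALSE)
    header <- rbind(header, add)
  }
  rownames(records) <- NULL
  rownames(header) <- NULL
  structure(list(records = records, header = header), class = "releve_table")
}

#' @export
print.releve_table <- function(x, ...) {
  cat("releve_table:", n_plots(x), "plots,", nrow(x$records), "records,",
      length(unique(normalize_name(x$records$taxon))), "taxa\n")
  invisible(x)
}

#' Number of plots in a releve table
#' @param table a `releve_table`.
#' @return integer plot count (plots listed in the header).
#' @export
n_plots <- function(table) {
  stopifnot(inherits(table, "releve_table"))
  nrow(table$header)
}

#' Plot identifiers of a releve table
#' @param table a `releve_table`.
#' @return character vector of plot ids.
#' @export
plot_ids <- function(table) {
  stopifnot(inherits(table, "releve_table"))
  table$header$plot_id
}

#' Restrict a releve table to a set of plots
#' @param table a `releve_table`.
#' @param plots character vector of plot ids to keep.
#' @return a `releve_table` with those plots (header rows kept even for
#'   plots without records).
#' @export
subset_releves <- function(table, plots) {
  stopifnot(inherits(table, "releve_table"))
  releve_table(table$records[table$records$plot_id %in% plots, , drop = FALSE],
               table$header[table$header$plot_id %in% plots, , drop = FALSE])
}

#' Read releves from species and header files
#'
#' The species file (CSV or TSV, delimiter sniffed) must have columns
#' `plot_id`, `taxon`, `layer`, `cover`; covers may be scale codes or
#' percentages and are converted with [convert_cover()]. The optional header
#' file has `plot_id` plus any of `lon`, `lat`, `area_m2`, `date`
#' (WGS84 decimal degrees, square metres, ISO dates). Plots present in the
#' species file but absent from the header carry empty header fields.
#'
#' @param species_path path to the long-format species file.
#' @param header_path optional path to the header file.
#' @param scale a [cover_scale()] used for code conversion.
#' @return a [releve_table()].
#' @export
read_releves <- function(species_path, header_path = NULL,
                         scale = bb_scale()) {
  sp <- read_delim_auto(species_path)
  req <- c("plot_id", "taxon", "layer", "cover")
  if (!all(req %in% names(sp))) {
    stop("species file needs columns: ", paste(req, collapse = ", "))
  }
  cover <- vector("numeric", nrow(sp))
  if (nrow(sp)) {
    cover <- tryCatch(convert_cover(sp$cover, scale), error = function(e) {
      # locate the first offending row for a useful message
      ok <- vapply(as.character(sp$cover), function(cd) {
        !inherits(tryCatch(convert_cover(cd, scale), error = identity),
                  "error")
      }, logical(1))
      i <- which(!ok)[1]
      stop("bad cover code '", sp$cover[i], "' in plot '", sp$plot_id[i],
           "', taxon '", sp$taxon[i], "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  rec <- data.frame(plot_id = sp$plot_id, taxon = sp$taxon, layer = sp$layer,
                    cover = cover, stringsAsFactors = FALSE)
  hdr <- if (!is.null(header_path)) read_delim_auto(header_path) else NULL
  releve_table(rec, hdr)
}

#' Write a releve table to species and header files
#'
#' Emits the same dialect [read_releves()] consumes (covers as percentages),
#' so a read/write cycle round-trips.
#'
#' @param table a `releve_table`.
#' @param species_path output path for species records (.csv or .tsv).
#' @param header_path optional output path for the header.
#' @return invisibly, the paths written.
#' @export
write_releves <- function(table, species_path, header_path = NULL) {
  stopifnot(inherits(table, "releve_table"))
  out <- table$records
  out$cover <- out$cover * 100
  write_delim_auto(out, species_path)
  if (!is.null(header_path)) write_delim_auto(table$header, header_path)
  invisible(c(species_path, header_path))
}

#' Read a taxon merge map from YAML
#'
#' The file is a flat mapping `source taxon: aggregate name`. The mapping
#' must be idempotent after one application: an aggregate name may not
#' itself be mapped elsewhere.
#'
#' @param path YAML file path.
#' @return named character vector (names = source taxa, values = aggregates).
#' @export
read_merge_map <- function(path) {
  y <- yaml::read_yaml(path)
  map <- vapply(y, as.character, character(1))
  validate_merge_map(map)
}

validate_merge_map <- function(map) {
  stopifnot(is.character(map), !is.null(names(map)))
  src <- normalize_name(names(map))
  dst <- normalize_name(map)
  moved <- dst %in% src & dst != src
  if (any(moved)) {
    stop("merge map is not idempotent: aggregate(s) ",
         paste(unique(map[moved]), collapse = ", "), " are also mapped")
  }
  map
}

#' Merge taxonomically critical taxa into aggregates
#'
#' Records whose taxon is in the merge map domain are renamed to their
#' aggregate. When several records of one plot and layer collapse onto one
#' aggregate their covers combine under the independence rule
#' `1 - prod(1 - c_i)` (see [combine_covers()]).
#'
#' @param table a `releve_table`.
#' @param merge named character vector or path readable by
#'   [read_merge_map()].
#' @return a `releve_table` with merged taxa.
#' @export
merge_taxa <- function(table, merge) {
  stopifnot(inherits(table, "releve_table"))
  if (is.character(merge) && is.null(names(merge)) && length(merge) == 1L) {
    merge <- read_merge_map(merge)
  }
  merge <- validate_merge_map(merge)
  rec <- table$records
  if (!nrow(rec)) return(table)
  idx <- match(normalize_name(rec$taxon), normalize_name(names(merge)))
  hit <- !is.na(idx)
  rec$taxon[hit] <- unname(merge[idx[hit]])
  key <- paste(rec$plot_id, rec$layer, normalize_name(rec$taxon), sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    comb <- vapply(split(rec$cover, key), combine_covers, numeric(1))
    out <- rec[first, , drop = FALSE]
    out$cover <- unname(comb[paste(out$plot_id, out$layer,
                                   normalize_name(out$taxon), sep = "\r")])
    rec <- out
  }
  releve_table(rec, table$header)
}

#' Plot-level filters
#'
#' Removes plots with missing coordinates (when `require_coords`) and plots
#' whose area falls outside `[min_area, max_area]` (bounds inclusive: areas
#' *smaller than* `min_area` or *greater than* `max_area` are excluded; a
#' plot with unknown area is excluded too). Records of cultivated species
#' are then dropped from the surviving plots; a plot emptied this way is
#' retained. Removal counts are attached as attribute `"filter_log"`.
#'
#' @param table a `releve_table`.
#' @param min_area,max_area area bounds in square metres.
#' @param require_coords drop plots without lon/lat?
#' @param cultivated character vector of cultivated species to remove.
#' @return the filtered `releve_table`.
#' @export
filter_releves <- function(table, min_area = 1, max_area = 100,
                           require_coords = TRUE,
                           cultivated = character()) {
  stopifnot(inherits(table, "releve_table"), min_area <= max_area)
  h <- table$header
  n_in <- nrow(h)
  keep <- rep(TRUE, n_in)
  no_coords <- is.na(h$lon) | is.na(h$lat)
  if (require_coords) keep <- keep & !no_coords
  bad_area <- is.na(h$area_m2) | h$area_m2 < min_area | h$area_m2 > max_area
  removed_coords <- sum(require_coords & no_coords)
  removed_area <- sum(keep & bad_area)
  keep <- keep & !bad_area
  plots <- h$plot_id[keep]
  rec <- table$records[table$records$plot_id %in% plots, , drop = FALSE]
  n_cult <- 0L
  if (length(cultivated)) {
    cult <- normalize_name(rec$taxon) %in% normalize_name(cultivated)
    n_cult <- sum(cult)
    rec <- rec[!cult, , drop = FALSE]
  }
  out <- releve_table(rec, h[keep, , drop = FALSE])
  attr(out, "filter_log") <- list(
    plots_in = n_in, plots_kept = length(plots),
    plots_removed_no_coords = removed_coords,
    plots_removed_area = removed_area,
    records_removed_cultivated = n_cult)
  out
}

#' Per-plot combined cover vectors
#'
#' Pools the layers of each species within a plot under the independence
#' rule and returns, per plot, a named vector of cover fractions keyed by
#' normalized taxon name. This is the representation the formal-definition
#' engine evaluates.
#'
#' @param table a `releve_table`.
#' @return named list (by plot id) of named numeric vectors.
#' @export
plot_covers <- function(table) {
  stopifnot(inherits(table, "releve_table"))
  rec <- table$records
  out <- stats::setNames(vector("list", n_plots(table)), plot_ids(table))
  for (p in names(out)) out[[p]] <- stats::setNames(numeric(0), character(0))
  if (!nrow(rec)) return(out)
  rec$ntaxon <- normalize_name(rec$taxon)
  by_plot <- split(rec[c("ntaxon", "cover")], rec$plot_id)
  for (p in names(by_plot)) {
    d <- by_plot[[p]]
    cov <- vapply(split(d$cover, d$ntaxon), combine_covers, numeric(1))
    out[[p]] <- cov
  }
  out
}

#' Combined cover vector of a single plot
#' @param table a `releve_table`.
#' @param plot plot id.
#' @return named numeric vector of cover fractions (normalized taxon names).
#' @export
releve_cover <- function(table, plot) {
  stopifnot(inherits(table, "releve_table"))
  if (!plot %in% plot_ids(table)) stop("unknown plot id: ", plot)
  rec <- table$records[table$records$plot_id == plot, , drop = FALSE]
  if (!nrow(rec)) return(stats::setNames(numeric(0), character(0)))
  vapply(split(rec$cover, normalize_name(rec$taxon)), combine_covers,
         numeric(1))
}
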
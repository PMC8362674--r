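#' Geographic grid specification
#'
#' Rectangular grid in geographic coordinates, anchored at (0, 0). The
#' default cell of 1.25' longitude x 0.75' latitude is roughly
#' 1.4 km x 1.4 km at 52 N, the cell size used for stratified resampling of
#' the reference survey. Degrees are available via `unit = "deg"`.
#'
#' @param width cell width (longitude).
#' @param height cell height (latitude).
#' @param unit `"arcmin"` or `"deg"`.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(width = 1.25, height = 0.75, unit = c("arcmin", "deg")) {
  unit <- match.arg(unit)
  stopifnot(width > 0, height > 0)
  structure(list(width = width, height = height, unit = unit),
            class = "grid_spec")
}

#' Grid cell indices of points
#'
#' `i = floor(lon / width)`, `j = floor(lat / height)` with lon/lat
#' converted to the grid's unit. Floor semantics: points an epsilon apart
#' across a cell edge land in different cells.
#'
#' @param lon,lat coordinates in decimal degrees (WGS84); vectorized.
#' @param grid a [grid_spec()].
#' @return data frame with integer columns `i`, `j`.
#' @export
grid_cell <- function(lon, lat, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(is.na(lon)) || any(is.na(lat))) {
    stop("missing coordinates: grid_cell needs lon and lat for every point")
  }
  f <- if (grid$unit == "arcmin") 60 else 1
  data.frame(i = as.integer(floor(lon * f / grid$width)),
             j = as.integer(floor(lat * f / grid$height)))
}

#' Geographic stratified resampling
#'
#' Within every (grid cell, unit) stratum, keeps at most `per_cell` plots,
#' chosen uniformly without replacement. Selection is reproducible under
#' `seed` and invariant to the input ordering (candidates are sorted by
#' plot id before sampling); the output table's plots are in sorted order.
#'
#' @param table a `releve_table`; labelled plots must have coordinates.
#' @param labels named character vector plot id -> unit; plots with `NA`
#'   labels are dropped.
#' @param grid a [grid_spec()].
#' @param per_cell maximum plots kept per (cell, unit) stratum.
#' @param seed RNG seed for the random selection (`NULL`: current RNG).
#' @return the resampled `releve_table`; the kept plot -> unit labelling is
#'   attached as attribute `"labels"`.
#' @export
stratified_sample <- function(table, labels, grid = grid_spec(),
                              per_cell = 3, seed = NULL) {
  stopifnot(inherits(table, "releve_table"), per_cell >= 1)
  labels <- labels[!is.na(labels)]
  plots <- intersect(plot_ids(table), names(labels))
  h <- table$header[match(plots, table$header$plot_id), , drop = FALSE]
  if (any(is.na(h$lon) | is.na(h$lat))) {
    stop("labelled plot(s) without coordinates cannot be stratified")
  }
  cell <- grid_cell(h$lon, h$lat, grid)
  stratum <- paste(cell$i, cell$j, labels[plots], sep = "\r")
  keep <- with_seed(seed, {
    unlist(lapply(split(plots, stratum), function(ids) {
      ids <- sort(ids)
      if (length(ids) <= per_cell) ids else sample(ids, per_cell)
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  out <- subset_releves(table, keep)
  # keep header/records in sorted plot order for deterministic output
  out$header <- out$header[order(out$header$plot_id), , drop = FALSE]
  rownames(out$header) <- NULL
  attr(out, "labels") <- labels[keep]
  out
}

#' Export per-unit occurrences as GeoJSON point collections
#'
#' One `FeatureCollection` of WGS84 points per unit, the map-ready
#' substitute for distribution maps. Features carry `plot_id` and `unit`
#' properties.
#'
#' @param table a `releve_table` with coordinates.
#' @param labels named character vector plot id -> unit.
#' @param dir output directory; one `units_<unit>.geojson` file per unit.
#' @return invisibly, the paths written.
#' @export
export_unit_geojson <- function(table, labels, dir) {
  stopifnot(inherits(table, "releve_table"))
  labels <- labels[!is.na(labels)]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (u in sort(unique(labels))) {
    uplots <- sort(intersect(names(labels)[labels == u], plot_ids(table)))
    h <- table$header[match(uplots, table$header$plot_id), , drop = FALSE]
    feats <- lapply(seq_along(uplots), function(k) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(h$lon[k], h$lat[k])),
           properties = list(plot_id = uplots[k], unit = u))
    })
    fc <- list(type = "FeatureCollection", features = feats)
    slug <- gsub("[^A-Za-z0-9]+", "_", u)
    path <- file.path(dir, paste0("units_", slug, ".geojson"))
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
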
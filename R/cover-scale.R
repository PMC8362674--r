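#' Cover-abundance scales
#'
#' A cover scale maps ordinal cover-abundance codes (e.g. Braun-Blanquet
#' `r, +, 1, ..., 5`) to percentage midpoints. Numeric percentages are always
#' accepted alongside the codes, so a scale only needs to enumerate the
#' non-numeric codes of its dialect.
#'
#' @param name scale name.
#' @param codes character vector of codes.
#' @param midpoints numeric vector of percentage midpoints, strictly
#'   increasing, each in `(0, 100]`.
#' @return an object of class `cover_scale`.
#' @seealso [bb_scale()], [convert_cover()], [read_cover_scale()]
#' @export
cover_scale <- function(name, codes, midpoints) {
  stopifnot(is.character(codes), is.numeric(midpoints),
            length(codes) == length(midpoints), length(codes) > 0L)
  if (any(midpoints <= 0) || any(midpoints > 100)) {
    stop("cover scale midpoints must lie in (0, 100]")
  }
  if (any(diff(midpoints) <= 0)) {
    stop("cover scale midpoints must be strictly increasing")
  }
  if (anyDuplicated(codes)) stop("duplicated cover codes in scale")
  structure(list(name = name, codes = codes, midpoints = midpoints),
            class = "cover_scale")
}

#' @export
print.cover_scale <- function(x, ...) {
  cat("Cover scale '", x$name, "': ",
      paste0(x$codes, "=", x$midpoints, "%", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default (old) Braun-Blanquet scale
#'
#' Midpoints: r = 0.1, + = 0.5, 1 = 2.5, 2 = 15, 3 = 37.5, 4 = 62.5,
#' 5 = 87.5 percent. The `5` midpoint is the centre of the 75-100 % class.
#' Replace with [cover_scale()] or a YAML file via [read_cover_scale()]
#' for other dialects.
#'
#' @return a `cover_scale`.
#' @export
bb_scale <- function() {
  cover_scale("braun_blanquet_old",
              codes = c("r", "+", "1", "2", "3", "4", "5"),
              midpoints = c(0.1, 0.5, 2.5, 15, 37.5, 62.5, 87.5))
}

#' Read a cover scale from YAML
#'
#' The file carries `name:` and a `codes:` mapping of code to percentage
#' midpoint. See `inst/extdata/braun_blanquet.yaml` for the packaged default.
#'
#' @param path YAML file path.
#' @return a `cover_scale`.
#' @export
read_cover_scale <- function(path) {
  y <- yaml::read_yaml(path)
  codes <- names(y$codes)
  mid <- as.numeric(unlist(y$codes, use.names = FALSE))
  ord <- order(mid)
  cover_scale(y$name %||% tools::file_path_sans_ext(basename(path)),
              codes[ord], mid[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert cover codes to cover fractions
#'
#' Codes listed in the scale are converted to their midpoint / 100; anything
#' else must parse as a percentage in `(0, 100]` and is divided by 100. A
#' recorded species cannot have zero cover, so `"0"` (and negative values)
#' are errors.
#'
#' @param code character (or numeric) vector of cover codes or percentages.
#' @param scale a [cover_scale()]; default [bb_scale()].
#' @return numeric vector of cover fractions in `(0, 1]`.
#' @examples
#' convert_cover(c("5", "+", "50"))  # 0.875 0.005 0.500
#' @export
convert_cover <- function(code, scale = bb_scale()) {
  stopifnot(inherits(scale, "cover_scale"))
  code <- trimws(as.character(code))
  idx <- match(code, scale$codes)
  out <- scale$midpoints[idx] / 100
  need <- is.na(idx)
  if (any(need)) {
    val <- suppressWarnings(as.numeric(code[need]))
    bad <- is.na(val)
    if (any(bad)) {
      stop("unknown cover code(s): ",
           paste(unique(code[need][bad]), collapse = ", "),
           " (scale '", scale$name, "')")
    }
    if (any(val <= 0 | val > 100)) {
      stop("numeric cover must be a percentage in (0, 100]; got: ",
           paste(unique(val[val <= 0 | val > 100]), collapse = ", "))
    }
    out[need] <- val / 100
  }
  out
}
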
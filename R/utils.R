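# Internal helpers shared across modules.

#' Combine covers of independently overlapping layers or taxa
#'
#' Cover fractions are combined under the assumption of independent random
#' overlap, `1 - prod(1 - c_i)`. The same rule is used when layers of one
#' species are pooled, when taxa are merged into an aggregate, and inside
#' the total-cover (#TC) group operator, so the three operations commute.
#'
#' @param covers numeric vector of cover fractions in `[0, 1]`.
#' @return a single cover fraction in `[0, 1]`.
#' @examples
#' combine_covers(c(0.5, 0.5))  # 0.75
#' @export
combine_covers <- function(covers) {
  stopifnot(is.numeric(covers), all(covers >= 0 & covers <= 1))
  if (length(covers) == 0L) return(0)
  1 - prod(1 - covers)
}

# Canonical form used for all taxon/group name matching: collapse runs of
# whitespace, trim, casefold. No fuzzy matching by design (determinism).
normalize_name <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Read a CSV or TSV file, sniffing the delimiter from the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "",
                    fileEncoding = "UTF-8")
}

write_delim_auto <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
}

#' Path to a packaged data file
#'
#' @param ... path components below `inst/extdata`.
#' @return absolute file path.
#' @export
vc_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "vegcocktail", mustWork = TRUE)
  p
}
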
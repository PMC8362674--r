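#' Community matrix from a releve table
#'
#' Plots x species matrix of percentage covers (layers of one species
#' pooled by the independence rule). All-zero rows and columns are pruned.
#'
#' @param table a `releve_table`.
#' @return numeric matrix (rows = plot ids, columns = taxon names).
#' @export
community_matrix <- function(table) {
  stopifnot(inherits(table, "releve_table"))
  rec <- table$records[table$records$cover > 0, , drop = FALSE]
  if (!nrow(rec)) stop("no non-zero records: empty community matrix")
  rec$ntaxon <- normalize_name(rec$taxon)
  display <- rec$taxon[!duplicated(rec$ntaxon)]
  names(display) <- rec$ntaxon[!duplicated(rec$ntaxon)]
  plots <- sort(unique(rec$plot_id))
  species <- sort(unique(rec$ntaxon))
  m <- matrix(0, length(plots), length(species),
              dimnames = list(plots, unname(display[species])))
  key <- paste(rec$plot_id, rec$ntaxon, sep = "\r")
  cov <- vapply(split(rec$cover, key), combine_covers, numeric(1))
  ij <- do.call(rbind, strsplit(names(cov), "\r", fixed = TRUE))
  m[cbind(match(ij[, 1], plots), match(ij[, 2], species))] <- 100 * cov
  m
}

#' Power transformation of covers
#'
#' Entrywise `b = x^p`; the default `p = 0.5` (square root) damps dominant
#' species before ordination. Zero stays zero; `p = 1` is the identity.
#'
#' @param m non-negative numeric matrix of percentage covers.
#' @param p exponent, `> 0`.
#' @return transformed matrix.
#' @export
transform_cover <- function(m, p = 0.5) {
  stopifnot(is.numeric(m), p > 0)
  if (any(m < 0)) stop("covers must be non-negative")
  m^p
}

#' Correspondence analysis
#'
#' Classical (chi-square) correspondence analysis by singular value
#' decomposition of the standardized residual matrix
#' `Q = D_r^{-1/2} (P - r c') D_c^{-1/2}` with `P = M / sum(M)`. Row and
#' column scores are standard coordinates (weighted variance 1 per axis);
#' eigenvalues are the squared singular values, in `[0, 1]` and
#' non-increasing. Axis signs are fixed deterministically.
#'
#' @param m non-negative matrix with positive total; all-zero rows/columns
#'   are pruned (rank-0 input is an error).
#' @param n_axes number of axes to keep (default: all non-trivial ones).
#' @return list of class `ca_result`: `eigenvalues`, `rscores`, `cscores`,
#'   `r`, `c` (row/column masses).
#' @export
ca <- function(m, n_axes = NULL) {
  stopifnot(is.matrix(m) || is.data.frame(m))
  m <- as.matrix(m)
  if (any(m < 0)) stop("community matrix entries must be >= 0")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (!length(m) || sum(m) <= 0 || nrow(m) < 2L || ncol(m) < 2L) {
    stop("degenerate community matrix (needs >= 2 non-empty rows and columns)")
  }
  gt <- sum(m)
  P <- m / gt
  r <- rowSums(P)
  cc <- colSums(P)
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(Q)
  eig <- sv$d^2
  keep <- which(eig > 1e-12)
  if (!length(keep)) {
    # no non-trivial structure (e.g. constant matrix): all eigenvalues 0
    k <- min(dim(m)) - 1L
    if (!is.null(n_axes)) k <- min(k, n_axes)
    rsc <- matrix(0, nrow(m), k, dimnames = list(rownames(m),
                                                 paste0("CA", seq_len(k))))
    csc <- matrix(0, ncol(m), k, dimnames = list(colnames(m),
                                                 paste0("CA", seq_len(k))))
    return(structure(list(eigenvalues = rep(0, k), rscores = rsc,
                          cscores = csc, r = r, c = cc),
                     class = "ca_result"))
  }
  if (!is.null(n_axes)) keep <- keep[seq_len(min(n_axes, length(keep)))]
  eig <- pmin(eig[keep], 1)
  rsc <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/")
  csc <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cc), "/")
  for (k in seq_along(keep)) {
    s <- axis_sign(rsc[, k], r)
    rsc[, k] <- s * rsc[, k]
    csc[, k] <- s * csc[, k]
  }
  dimnames(rsc) <- list(rownames(m), paste0("CA", seq_along(keep)))
  dimnames(csc) <- list(colnames(m), paste0("CA", seq_along(keep)))
  structure(list(eigenvalues = eig, rscores = rsc, cscores = csc,
                 r = r, c = cc),
            class = "ca_result")
}

# Deterministic, permutation-invariant sign convention: positive weighted
# skewness; ties broken by the score of the alphabetically first row.
axis_sign <- function(x, w) {
  s <- sum(w * x^3)
  if (abs(s) > 1e-10) return(sign(s))
  nm <- names(x)
  v <- if (!is.null(nm)) x[order(nm)][1] else x[1]
  if (v < 0) -1 else 1
}

#' @export
print.ca_result <- function(x, ...) {
  cat("correspondence analysis:", nrow(x$rscores), "plots,",
      nrow(x$cscores), "species; eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 4), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Detrending by segments
#'
#' Splits the range of the primary axis into `n_segments` equal-width
#' segments and subtracts, within each segment, the segment mean of the
#' target scores (Hill-style detrending). With one segment this is global
#' mean centring.
#'
#' @param primary scores of the axis detrended against.
#' @param target scores to detrend; aligned with `primary`.
#' @param n_segments number of segments (>= 1).
#' @return detrended target scores.
#' @export
detrend_segments <- function(primary, target, n_segments = 26) {
  stopifnot(length(primary) == length(target), n_segments >= 1)
  rng <- range(primary)
  if (diff(rng) == 0) return(target - mean(target))
  breaks <- seq(rng[1], rng[2], length.out = n_segments + 1L)
  idx <- findInterval(primary, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  target - stats::ave(target, idx)
}

#' Detrended correspondence analysis
#'
#' Axis 1 is the first CA axis. Each further axis is extracted by iterated
#' two-way weighted averaging (reciprocal averaging) in which, at every
#' iteration, the trial scores are detrended by segments against all
#' previously extracted axes, then recentred and rescaled to unit weighted
#' norm. The eigenvalue of a detrended axis is the contraction rate of the
#' converged iteration. Hill's nonlinear rescaling is not applied by
#' default (`rescale` reserves the flag; only `FALSE` is implemented).
#'
#' Convergence is deterministic (initialised from the corresponding CA
#' axis), so results are seed-free. When the iteration does not settle
#' within `max_iter` steps — typical for degenerate data whose detrended
#' operator has a complex dominant eigenpair, e.g. a pure single gradient
#' whose arch the detrending annihilates — the axis is computed directly:
#' the detrended reciprocal-averaging step is a fixed linear operator, so
#' its dominant essentially-real eigenvector (the limit the iteration
#' seeks) is taken from an explicit eigen decomposition.
#'
#' @param m community matrix (plots x species, non-negative).
#' @param n_axes number of axes (default 4).
#' @param n_segments detrending segments (default 26).
#' @param tol convergence tolerance on the score change.
#' @param max_iter iteration cap per axis.
#' @param rescale must be `FALSE`.
#' @return list of class `dca_result`: `eigenvalues`, `site_scores`,
#'   `species_scores`, `n_segments`.
#' @export
dca <- function(m, n_axes = 4, n_segments = 26, tol = 1e-10,
                max_iter = 10000, rescale = FALSE) {
  if (!identical(rescale, FALSE)) {
    stop("nonlinear rescaling is not implemented; use rescale = FALSE")
  }
  m <- as.matrix(m)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  base <- ca(m)
  n_axes <- min(n_axes, length(base$eigenvalues))
  r <- base$r
  rs <- rowSums(m)
  cs <- colSums(m)
  wnorm <- function(x) sqrt(sum(r * x^2))
  scores <- matrix(0, nrow(m), n_axes,
                   dimnames = list(rownames(m), paste0("DCA", 1:n_axes)))
  eig <- numeric(n_axes)
  scores[, 1] <- base$rscores[, 1]
  eig[1] <- base$eigenvalues[1]
  if (n_axes > 1) {
    for (ax in 2:n_axes) {
      # one detrended reciprocal-averaging step (a fixed linear map)
      ra_step <- function(x) {
        y <- as.numeric(crossprod(m, x)) / cs     # species WA of sites
        xn <- as.numeric(m %*% y) / rs            # site WA of species
        # detrending against any previous axis annihilates constant
        # vectors, so the trivial CA axis needs no separate centring
        for (p in seq_len(ax - 1L)) {
          xn <- detrend_segments(scores[, p], xn, n_segments)
        }
        xn
      }
      x <- base$rscores[, min(ax, ncol(base$rscores))]
      lambda <- NA_real_
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        xn <- ra_step(x)
        lambda <- wnorm(xn)
        if (lambda < 1e-14) break
        xn <- xn / lambda
        if (max(abs(xn - x)) < tol || max(abs(-xn - x)) < tol) {
          x <- xn
          converged <- TRUE
          break
        }
        x <- xn
      }
      if (!converged) {
        sol <- ra_dominant_eigen(ra_step, length(x), r)
        if (is.null(sol)) {
          stop("DCA axis ", ax, " did not converge within ", max_iter,
               " iterations (tol ", tol,
               ") and has no real dominant eigenpair")
        }
        x <- sol$vector
        lambda <- sol$value
      }
      s <- axis_sign(x, r)
      scores[, ax] <- s * x
      eig[ax] <- min(max(lambda, 0), 1)
    }
  }
  species <- sweep(crossprod(m, scores), 1, cs, "/")
  colnames(species) <- colnames(scores)
  structure(list(eigenvalues = eig, site_scores = scores,
                 species_scores = species, n_segments = n_segments),
            class = "dca_result")
}

# Assemble the detrended reciprocal-averaging operator column by column and
# return its dominant essentially-real eigenpair (weighted-norm-1 vector),
# or NULL when every usable eigenvalue is complex.
ra_dominant_eigen <- function(ra_step, n, r) {
  A <- vapply(seq_len(n), function(i) ra_step(replace(numeric(n), i, 1)),
              numeric(n))
  e <- eigen(A)
  real_ok <- abs(Im(e$values)) < 1e-8 * (1 + abs(Re(e$values)))
  usable <- which(real_ok & Re(e$values) > 1e-14)
  if (!length(usable)) return(NULL)
  k <- usable[which.max(Re(e$values)[usable])]
  x <- Re(e$vectors[, k])
  nx <- sqrt(sum(r * x^2))
  if (nx < 1e-14) return(NULL)
  list(value = Re(e$values[k]), vector = x / nx)
}

#' @export
print.dca_result <- function(x, ...) {
  cat("DCA:", nrow(x$site_scores), "plots,", nrow(x$species_scores),
      "species;", x$n_segments, "segments; eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Read an indicator-value table
#'
#' CSV with a `species` column and one column per indicator — by
#' convention `L` (light), `T` (temperature), `K` (continentality),
#' `F` (moisture), `R` (soil reaction), `N` (nutrients) — with blanks for
#' missing values. The packaged `eiv_synthetic.csv` is a synthetic stand-in
#' with plausible values for ephemeral wetland species; it exercises the
#' code paths but is not the published indicator table.
#'
#' @param path CSV file.
#' @return data frame with `species` plus numeric indicator columns.
#' @export
read_eiv <- function(path) {
  df <- read_delim_auto(path)
  if (!"species" %in% names(df)) stop("indicator table needs a species column")
  for (cn in setdiff(names(df), "species")) {
    df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  }
  df
}

#' Community-weighted mean indicator values
#'
#' Per plot and indicator: `sum(cover_i * v_i) / sum(cover_i)` over the
#' species that have a value for that indicator (species without a value
#' are excluded from both sums). A plot with no valued species gets `NA`
#' for that indicator. `weighted = FALSE` gives the unweighted mean over
#' the present valued species.
#'
#' @param table a `releve_table`.
#' @param eiv indicator table ([read_eiv()]).
#' @param indicators indicator columns to use (default: all non-`species`).
#' @param weighted cover-weighted (CWM, default) or unweighted mean.
#' @return data frame: one row per plot, `plot_id` plus indicator columns.
#' @export
cwm_eiv <- function(table, eiv, indicators = NULL, weighted = TRUE) {
  stopifnot(inherits(table, "releve_table"))
  indicators <- indicators %||% setdiff(names(eiv), "species")
  covs <- plot_covers(table)
  key <- normalize_name(eiv$species)
  out <- data.frame(plot_id = names(covs), stringsAsFactors = FALSE)
  for (ind in indicators) {
    vals <- stats::setNames(eiv[[ind]], key)
    out[[ind]] <- vapply(covs, function(cv) {
      v <- vals[names(cv)]
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      w <- if (weighted) cv[ok] else rep(1, sum(ok))
      sum(w * v[ok]) / sum(w)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Fit indicator values as supplementary variables
#'
#' For each indicator, finds the least-squares direction in axis space
#' maximizing the correlation with the plot values (a linear fit of the
#' indicator on the site scores), and reports the unit direction vector,
#' the squared correlation r2 and a permutation p-value (indicator values
#' permuted across plots). Plots with missing values are dropped from that
#' indicator's fit. A constant indicator gets r2 = 0, p = 1.
#'
#' @param ord a `dca_result` or `ca_result`, or a site-score matrix.
#' @param env data frame of plot values; a `plot_id` column, if present,
#'   aligns rows with the score matrix (otherwise rows must align already).
#' @param permutations number of permutations (>= 99 recommended, default
#'   999).
#' @param seed RNG seed for the permutations.
#' @return data frame of class `supplementary_fit`: `indicator`, one
#'   direction column per axis, `r2`, `p`, `n`.
#' @export
fit_supplementary <- function(ord, env, permutations = 999, seed = NULL) {
  scores <- if (inherits(ord, "dca_result")) ord$site_scores
  else if (inherits(ord, "ca_result")) ord$rscores
  else as.matrix(ord)
  env <- as.data.frame(env)
  if ("plot_id" %in% names(env)) {
    env <- env[match(rownames(scores), env$plot_id), , drop = FALSE]
    env$plot_id <- NULL
  }
  if (nrow(env) != nrow(scores)) {
    stop("env rows must align with the score matrix")
  }
  axes <- colnames(scores) %||% paste0("Axis", seq_len(ncol(scores)))
  with_seed(seed, {
    rows <- lapply(names(env), function(ind) {
      v <- as.numeric(env[[ind]])
      ok <- !is.na(v)
      if (sum(ok) < 3L) {
        stop("indicator '", ind, "' has fewer than 3 plots with values")
      }
      X <- scores[ok, , drop = FALSE]
      y <- v[ok]
      r2v <- suppl_r2(X, y)
      dir <- r2v$dir
      r2 <- r2v$r2
      if (r2 == 0) {
        p <- 1
      } else {
        exceed <- sum(vapply(seq_len(permutations), function(k) {
          suppl_r2(X, sample(y))$r2 >= r2
        }, logical(1)))
        p <- (1 + exceed) / (permutations + 1)
      }
      out <- data.frame(indicator = ind, stringsAsFactors = FALSE)
      for (a in seq_along(axes)) out[[axes[a]]] <- dir[a]
      out$r2 <- r2
      out$p <- p
      out$n <- sum(ok)
      out
    })
    res <- do.call(rbind, rows)
    class(res) <- c("supplementary_fit", "data.frame")
    res
  })
}

suppl_r2 <- function(X, y) {
  if (stats::sd(y) == 0) {
    return(list(r2 = 0, dir = rep(0, ncol(X))))
  }
  fit <- stats::lm.fit(cbind(1, X), y)
  b <- fit$coefficients[-1]
  b[is.na(b)] <- 0
  yhat <- fit$fitted.values
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  nb <- sqrt(sum(b^2))
  dir <- if (nb > 0) b / nb else rep(0, ncol(X))
  list(r2 = max(0, min(1, r2)), dir = unname(dir))
}
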
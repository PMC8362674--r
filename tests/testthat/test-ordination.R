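# Deterministic coenocline: Gaussian species responses along one gradient.
coenocline <- function(n_plots = 50, n_species = 25, sd = 1, max_cov = 50) {
  grad <- seq(0, 10, length.out = n_plots)
  optima <- seq(0.5, 9.5, length.out = n_species)
  m <- outer(grad, optima, function(g, o) max_cov * exp(-(g - o)^2 / (2 * sd^2)))
  dimnames(m) <- list(sprintf("p%02d", seq_len(n_plots)),
                      sprintf("s%02d", seq_len(n_species)))
  list(m = m, gradient = grad)
}

test_that("cover transformation is an entrywise power with zero fixed", {
  m <- matrix(c(25, 0, 4, 100), 2)
  expect_equal(transform_cover(m), matrix(c(5, 0, 2, 10), 2))
  expect_equal(transform_cover(m, p = 1), m)
  expect_equal(transform_cover(0, p = 0.5), 0)
  expect_error(transform_cover(matrix(c(-1, 1), 1)), "non-negative")
  expect_error(transform_cover(m, p = 0))
})

test_that("CA eigenvalues and scores satisfy the transition formulas", {
  set.seed(8)
  m <- matrix(rpois(6 * 8, 3), 6, 8,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:8)))
  res <- ca(m)
  expect_true(all(res$eigenvalues >= 0 & res$eigenvalues <= 1))
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  # row scores are the eigenvalue-scaled weighted means of column scores
  P <- m / sum(m)
  for (k in seq_along(res$eigenvalues)) {
    lam <- res$eigenvalues[k]
    if (lam < 1e-8) next
    wa <- as.numeric((P %*% res$cscores[, k]) / res$r)
    expect_lt(max(abs(wa / sqrt(lam) - res$rscores[, k])), 1e-8)
  }
  # weighted variance of each axis is 1 (standard coordinates)
  expect_equal(unname(colSums(res$r * res$rscores^2)),
               rep(1, length(res$eigenvalues)), tolerance = 1e-10)
})

test_that("CA eigenvalues match a dense eigen-decomposition oracle", {
  set.seed(19)
  for (i in 1:5) {
    nr <- sample(5:20, 1); nc <- sample(5:30, 1)
    m <- matrix(rpois(nr * nc, 2) + rbinom(nr * nc, 1, 0.2), nr, nc)
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    if (nrow(m) < 3 || ncol(m) < 3) next
    res <- ca(m)
    P <- m / sum(m)
    r <- rowSums(P); cc <- colSums(P)
    Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
    ev <- sort(eigen(crossprod(Q), only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(res$eigenvalues,
                 ev[seq_along(res$eigenvalues)], tolerance = 1e-8)
  }
})

test_that("CA agrees with vegan's correspondence analysis", {
  set.seed(4)
  m <- matrix(rpois(10 * 12, 2), 10, 12,
              dimnames = list(paste0("r", 1:10), paste0("c", 1:12)))
  m <- m[rowSums(m) > 0, colSums(m) > 0]
  res <- ca(m)
  vg <- vegan::cca(m)
  expect_equal(unname(res$eigenvalues[1:4]), unname(vg$CA$eig[1:4]),
               tolerance = 1e-10)
})

test_that("two disjoint plot blocks give a unit first eigenvalue", {
  m <- rbind(cbind(matrix(5, 3, 4), matrix(0, 3, 4)),
             cbind(matrix(0, 3, 4), matrix(5, 3, 4)))
  dimnames(m) <- list(paste0("p", 1:6), paste0("s", 1:8))
  expect_equal(ca(m)$eigenvalues[1], 1)
  # axis-1 sign separates the blocks perfectly
  sc <- ca(m)$rscores[, 1]
  expect_equal(length(unique(sign(sc[1:3]))), 1L)
  expect_true(all(sign(sc[1:3]) != sign(sc[4:6])))
})

test_that("a constant matrix has all-zero eigenvalues", {
  m <- matrix(7, 4, 5, dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
  res <- ca(m)
  expect_true(all(res$eigenvalues == 0))
  expect_error(ca(matrix(0, 3, 3)), "degenerate")
})

test_that("detrending by segments removes segment means", {
  x <- seq(0, 1, length.out = 120)
  # constant target vanishes
  expect_equal(detrend_segments(x, rep(3.5, 120)), rep(0, 120))
  # one segment = global centring
  y <- rnorm(120)
  expect_equal(detrend_segments(x, y, 1), y - mean(y))
  # quadratic arch: recomputed segment means are ~0
  arch <- (x - 0.5)^2
  det <- detrend_segments(x, arch, 26)
  breaks <- seq(min(x), max(x), length.out = 27)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  expect_lt(max(abs(tapply(det, idx, mean))), 1e-10)
})

test_that("DCA recovers a single gradient exactly in rank order", {
  cl <- coenocline()
  d <- dca(transform_cover(cl$m), n_axes = 3)
  r1 <- rank(d$site_scores[, 1])
  expect_true(all(r1 == rank(cl$gradient)) ||
              all(r1 == rank(-cl$gradient)))
  expect_true(all(d$eigenvalues >= 0 & d$eigenvalues <= 1))
  # axis 2 is detrended against axis 1: segment means vanish
  breaks <- seq(min(d$site_scores[, 1]), max(d$site_scores[, 1]),
                length.out = d$n_segments + 1)
  idx <- findInterval(d$site_scores[, 1], breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  expect_lt(max(abs(tapply(d$site_scores[, 2], idx, mean))), 1e-10)
})

test_that("DCA is invariant to plot and species permutations", {
  ds <- generate_releves(n_per_unit = 8, seed = 31)
  m <- transform_cover(community_matrix(ds$table))
  d1 <- dca(m, n_axes = 2)
  set.seed(1)
  m2 <- m[sample(nrow(m)), sample(ncol(m))]
  d2 <- dca(m2, n_axes = 2)
  expect_equal(d1$eigenvalues, d2$eigenvalues, tolerance = 1e-8)
  expect_same_scores(d1$site_scores,
                     d2$site_scores[rownames(d1$site_scores), ])
})

test_that("axis-1 sign splits two well-separated clusters", {
  ds <- generate_releves(n_per_unit = 12, seed = 13)
  units <- unique(ds$labels)[c(1, 11)]  # different alliances
  keep <- names(ds$labels)[ds$labels %in% units]
  m <- transform_cover(community_matrix(subset_releves(ds$table, keep)))
  d <- dca(m, n_axes = 2)
  s <- d$site_scores[, 1]
  g <- ds$labels[rownames(d$site_scores)]
  expect_true(max(tapply(sign(s), g, function(z) length(unique(z)))) == 1)
})

test_that("community-weighted means average indicator values by cover", {
  rec <- data.frame(plot_id = c("p1", "p1", "p2", "p3", "p3"),
                    taxon = c("Aster alpha", "Bellis beta", "Aster alpha",
                              "Aster alpha", "Crepis gamma"),
                    layer = "herb", cover = c(0.5, 0.5, 0.30, 0.75, 0.25),
                    stringsAsFactors = FALSE)
  tb <- releve_table(rec)
  eiv <- data.frame(species = c("Aster alpha", "Bellis beta"),
                    F = c(4, 6), N = c(7, NA), stringsAsFactors = FALSE)
  cwm <- cwm_eiv(tb, eiv)
  expect_equal(cwm$F[cwm$plot_id == "p1"], 5.0)
  expect_equal(cwm$N[cwm$plot_id == "p1"], 7.0)  # NA species excluded
  expect_equal(cwm$F[cwm$plot_id == "p2"], 4.0)  # single species
  # 0.75/0.25 with values 4/8 -> 5; Crepis has no value, so only Aster
  eiv2 <- data.frame(species = c("Aster alpha", "Crepis gamma"),
                     F = c(4, 8), stringsAsFactors = FALSE)
  expect_equal(cwm_eiv(tb, eiv2)$F[3], (0.75 * 4 + 0.25 * 8) / 1)
  # bounded by contributing species values
  expect_true(all(cwm$F >= 4 & cwm$F <= 6, na.rm = TRUE))
  # unweighted mode
  cwm_u <- cwm_eiv(tb, eiv2, weighted = FALSE)
  expect_equal(cwm_u$F[3], 6)
})

test_that("supplementary fits recover aligned, noise and constant cases", {
  cl <- coenocline()
  d <- dca(transform_cover(cl$m), n_axes = 2)
  env <- data.frame(plot_id = rownames(d$site_scores),
                    aligned = d$site_scores[, 1],
                    const = 5,
                    stringsAsFactors = FALSE)
  fit <- fit_supplementary(d, env, permutations = 199, seed = 2)
  al <- fit[fit$indicator == "aligned", ]
  expect_equal(al$r2, 1, tolerance = 1e-10)
  expect_equal(abs(al$DCA1), 1, tolerance = 1e-8)
  expect_lt(al$p, 0.01)
  co <- fit[fit$indicator == "const", ]
  expect_equal(co$r2, 0)
  expect_equal(co$p, 1)
  # pure-noise indicators are not significant on average
  set.seed(99)
  ps <- replicate(20, {
    env_n <- data.frame(plot_id = rownames(d$site_scores),
                        noise = rnorm(nrow(d$site_scores)))
    fit_supplementary(d, env_n, permutations = 99)$p
  })
  expect_gt(median(ps), 0.1)
  expect_gt(mean(ps > 0.05), 0.5)
})
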
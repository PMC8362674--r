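# Independent oracles: phi as the Pearson correlation of the two 0/1
# indicator vectors; Fisher p as an explicit hypergeometric enumeration sum.
phi_oracle <- function(N, Np, n, np) {
  unit <- c(rep(1, Np), rep(0, N - Np))
  species <- c(rep(1, np), rep(0, Np - np),
               rep(1, n - np), rep(0, N - Np - (n - np)))
  suppressWarnings(stats::cor(unit, species))
}

fisher_oracle <- function(N, Np, n, np) {
  ks <- np:min(n, Np)
  sum(exp(lchoose(Np, ks) + lchoose(N - Np, n - ks) - lchoose(N, n)))
}

test_that("phi matches its closed form on the printed examples", {
  expect_equal(phi_fidelity(10, 5, 5, 5), 1.0)
  expect_equal(phi_fidelity(10, 5, 4, 4), 20 / sqrt(600))
  expect_equal(round(phi_fidelity(10, 5, 4, 4), 4), 0.8165)
  expect_equal(phi_fidelity(10, 5, 10, 5), 0)   # ubiquitous species
  expect_equal(phi_fidelity(10, 5, 0, 0), 0)    # absent species
  expect_equal(phi_fidelity(10, 10, 4, 4), 0)   # universal unit
  expect_error(phi_fidelity(10, 5, 4, 6), "inconsistent")
})

test_that("phi is antisymmetric under swapping unit and complement", {
  set.seed(3)
  for (i in 1:200) {
    N <- sample(5:40, 1)
    Np <- sample(1:(N - 1), 1)
    n <- sample(0:N, 1)
    np_range <- max(0, n + Np - N):min(n, Np)
    np <- np_range[sample.int(length(np_range), 1)]
    expect_equal(phi_fidelity(N, Np, n, np),
                 -phi_fidelity(N, N - Np, n, n - np), tolerance = 1e-12)
  }
})

test_that("one-sided Fisher matches exhaustive enumeration examples", {
  expect_equal(fisher_one_sided(10, 5, 4, 4), 5 / 210)
  expect_equal(fisher_one_sided(10, 5, 4, 0), 1.0)
  expect_equal(fisher_one_sided(10, 10, 4, 4), 1.0)  # unit = whole data set
  # cross-check against stats::fisher.test on a handful of tables
  for (tab in list(c(20, 8, 10, 7), c(30, 10, 15, 2), c(12, 6, 6, 6))) {
    ft <- stats::fisher.test(matrix(c(tab[4], tab[3] - tab[4],
                                      tab[2] - tab[4],
                                      tab[1] - tab[2] - tab[3] + tab[4]), 2),
                             alternative = "greater")
    expect_equal(fisher_one_sided(tab[1], tab[2], tab[3], tab[4]),
                 unname(ft$p.value), tolerance = 1e-10)
  }
})

test_that("fisher p decreases strictly as concentration np grows", {
  N <- 40; Np <- 15; n <- 20
  ps <- fisher_one_sided(N, Np, rep(n, 16), 0:15)
  expect_true(all(diff(ps) < 0))
})

test_that("synoptic tables recount the labelled data correctly", {
  tu <- two_unit_table(5, 5)
  syn <- build_synoptic(tu$table, tu$labels)
  a_x <- syn[syn$unit == "X" & syn$species == "Aster alpha", ]
  expect_equal(a_x$freq, 100)
  expect_equal(a_x$phi, 1)
  c_x <- syn[syn$unit == "X" & syn$species == "Crepis gamma", ]
  expect_equal(c_x$freq, 0)
  expect_lte(c_x$phi, 0)
  b_x <- syn[syn$unit == "X" & syn$species == "Bellis beta", ]
  expect_equal(b_x$phi, 0)  # shared by all plots
  # frequency example: species in 4 of 5 unit plots
  tb <- tu$table
  tb$records <- tb$records[!(tb$records$plot_id == "x01" &
                             tb$records$taxon == "Aster alpha"), ]
  syn2 <- build_synoptic(releve_table(tb$records, tb$header), tu$labels)
  expect_equal(syn2[syn2$unit == "X" & syn2$species == "Aster alpha", ]$freq,
               80)
  expect_error(build_synoptic(tu$table,
                              c(tu$labels, zz = "X")), "not in table")
})

test_that("synoptic phi and p equal brute-force recounts on 3 units", {
  ds <- generate_releves(n_per_unit = 8, seed = 21)
  keep <- ds$labels[ds$labels %in% unique(ds$labels)[1:3]]
  tb <- subset_releves(ds$table, names(keep))
  syn <- build_synoptic(tb, keep)
  covs <- plot_covers(tb)
  N <- length(keep)
  for (i in sample(nrow(syn), 40)) {
    u <- syn$unit[i]
    sp <- tolower(syn$species[i])
    pres <- vapply(covs[names(keep)], function(cv)
      sp %in% names(cv)[cv > 0], logical(1))
    Np <- sum(keep == u)
    n <- sum(pres)
    np <- sum(pres & keep == u)
    expect_equal(syn$np[i], np)
    expect_equal(syn$phi[i],
                 if (is.na(phi_oracle(N, Np, n, np))) 0
                 else phi_oracle(N, Np, n, np), tolerance = 1e-12)
    expect_equal(syn$p[i], fisher_oracle(N, Np, n, np), tolerance = 1e-12)
  }
  # partition property: per-species np sums to n across units
  agg <- tapply(syn$np, syn$species, sum)
  nref <- tapply(syn$n, syn$species, function(x) x[1])
  expect_equal(unname(agg[names(nref)]), unname(nref))
})

test_that("species roles honour the printed thresholds", {
  # 60 plots: unit U (10 plots) vs rest; species profiles engineered
  plots <- sprintf("q%02d", 1:60)
  labels <- stats::setNames(rep(c("U", "V"), c(10, 50)), plots)
  rec <- do.call(rbind, lapply(1:60, function(i) {
    sp <- character(0); cv <- numeric(0)
    if (i <= 10) { sp <- c(sp, "Cyperus fuscus"); cv <- c(cv, 0.10) }
    if (i <= 10) { sp <- c(sp, "Salix alba"); cv <- c(cv, 0.10) }
    if (i == 1)  { sp <- c(sp, "Lythrum portula"); cv <- c(cv, 0.30) }
    sp <- c(sp, "Juncus bufonius"); cv <- c(cv, 0.05)
    data.frame(plot_id = plots[i], taxon = sp, layer = "herb", cover = cv,
               stringsAsFactors = FALSE)
  }))
  tb <- releve_table(rec)
  syn <- build_synoptic(tb, labels)
  roles <- species_roles(syn, tb, labels, c(U = "association",
                                            V = "association"))
  u <- function(sp) roles[roles$unit == "U" & roles$species == sp, ]
  # exclusive class-list species: diagnostic + constant
  expect_true(u("Cyperus fuscus")$diagnostic)
  expect_true(u("Cyperus fuscus")$constant)
  expect_false(u("Cyperus fuscus")$differential)
  # same fidelity but not in the 63-species list: differential
  expect_true(u("Salix alba")$differential)
  expect_false(u("Salix alba")$diagnostic)
  # shared companion: neither
  expect_false(u("Juncus bufonius")$diagnostic ||
               u("Juncus bufonius")$differential)
  # 30 % cover in 1 of 10 unit plots: dominant (10 % >= 5 %), not constant
  expect_true(u("Lythrum portula")$dominant)
  expect_false(u("Lythrum portula")$constant)
  # alliance vs association threshold: phi in [0.20, 0.25) flips the call
  thr <- role_thresholds()
  syn_mod <- syn[syn$unit == "U" & syn$species == "Cyperus fuscus", ]
  syn_mod$phi <- 0.22
  syn_mod$p <- 1e-4
  class(syn_mod) <- class(syn)
  as_assoc <- species_roles(syn_mod, tb, labels, c(U = "association"), thr)
  as_alli <- species_roles(syn_mod, tb, labels, c(U = "alliance"), thr)
  expect_false(as_assoc$diagnostic)
  expect_true(as_alli$diagnostic)
})

test_that("standardized phi equalizes unit sizes", {
  # same within/without occurrence rates, different unit sizes
  # occurrence rates 0.8 inside / 0.15 outside, at unit sizes 20 and 50
  expect_equal(phi_fidelity(100, 20, 28, 16, standardize = TRUE),
               phi_fidelity(100, 50, 47.5, 40, standardize = TRUE),
               tolerance = 1e-12)
})
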
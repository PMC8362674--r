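# Small in-code fixtures shared across test files.

# A hand-built four-plot table: two wet-mud plots, one dwarf-rush plot,
# one plot of companions only.
tiny_table <- function() {
  rec <- data.frame(
    plot_id = c("p1", "p1", "p1", "p2", "p2", "p3", "p3", "p3", "p4"),
    taxon = c("Cyperus fuscus", "Limosella aquatica", "Juncus bufonius",
              "Cyperus fuscus", "Potentilla supina",
              "Isolepis setacea", "Juncus tenageia", "Stellaria alsine",
              "Juncus bufonius"),
    layer = "herb",
    cover = c(0.45, 0.20, 0.05, 0.60, 0.10, 0.35, 0.15, 0.05, 0.02),
    stringsAsFactors = FALSE)
  hdr <- data.frame(
    plot_id = c("p1", "p2", "p3", "p4"),
    lon = c(16.00, 16.01, 15.20, 17.00),
    lat = c(52.00, 52.00, 51.80, 51.00),
    area_m2 = c(10, 25, 4, 50),
    date = c("2018-08-01", "2018-08-02", "2019-07-15", "2017-09-01"),
    stringsAsFactors = FALSE)
  releve_table(rec, hdr)
}

# Registry with one group of each kind, for engine unit tests.
tiny_groups <- function() {
  list(
    Mud = species_group("Mud", "TC",
                        c("Cyperus fuscus", "Limosella aquatica",
                          "Potentilla supina")),
    Peak = species_group("Peak", "SC",
                         c("Cyperus fuscus", "Limosella aquatica")),
    Rush = species_group("Rush", "SOC",
                         c("Isolepis setacea", "Juncus tenageia",
                           "Stellaria alsine"))
  )
}

# Deterministic labelled two-unit table for fidelity tests: species "A"
# confined to unit X, "B" shared, "C" confined to unit Y.
two_unit_table <- function(nx = 5, ny = 5) {
  plots <- c(sprintf("x%02d", seq_len(nx)), sprintf("y%02d", seq_len(ny)))
  rec <- do.call(rbind, lapply(seq_along(plots), function(i) {
    p <- plots[i]
    inx <- i <= nx
    sp <- c(if (inx) "Aster alpha", "Bellis beta", if (!inx) "Crepis gamma")
    data.frame(plot_id = p, taxon = sp, layer = "herb",
               cover = rep(0.3, length(sp)), stringsAsFactors = FALSE)
  }))
  list(table = releve_table(rec),
       labels = stats::setNames(rep(c("X", "Y"), c(nx, ny)), plots))
}

expect_same_scores <- function(a, b, tol = 1e-8) {
  expect_equal(dim(a), dim(b))
  for (k in seq_len(ncol(a))) {
    expect_lt(min(max(abs(a[, k] - b[, k])), max(abs(a[, k] + b[, k]))), tol)
  }
}
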
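test_that("total cover pools member covers by independence", {
  g <- tiny_groups()$Mud
  cov <- c("cyperus fuscus" = 0.5, "limosella aquatica" = 0.5)
  expect_equal(total_cover(cov, g), 75)
  expect_equal(total_cover(c("juncus bufonius" = 0.9), g), 0)
  expect_equal(total_cover(c("cyperus fuscus" = 1.0,
                             "limosella aquatica" = 0.3), g), 100)
  # monotone: adding a member never decreases it
  set.seed(5)
  for (i in 1:20) {
    base <- c("cyperus fuscus" = runif(1))
    more <- c(base, "potentilla supina" = runif(1))
    expect_gte(total_cover(more, g), total_cover(base, g))
  }
})

test_that("single cover takes the member maximum", {
  g <- tiny_groups()$Peak
  expect_equal(max_single_cover(c("cyperus fuscus" = 0.30,
                                  "limosella aquatica" = 0.10), g), 30)
  expect_equal(max_single_cover(c("isolepis setacea" = 0.9), g), 0)
  expect_equal(max_single_cover(c("limosella aquatica" = 0.55), g), 55)
})

test_that("single cover <= total cover <= capped member sum", {
  g_tc <- tiny_groups()$Mud
  g_sc <- species_group("MudSC", "SC", g_tc$members)
  set.seed(11)
  for (i in 1:50) {
    cov <- stats::setNames(runif(3), g_tc$norm_members)
    tc <- total_cover(cov, g_tc)
    expect_lte(max_single_cover(cov, g_sc), tc + 1e-12)
    expect_lte(tc, min(100, 100 * sum(cov)) + 1e-9)
  }
})

test_that("sociological presence defaults to half the members, rounded up", {
  g3 <- tiny_groups()$Rush
  expect_true(sociological_presence(
    c("isolepis setacea" = 0.2, "juncus tenageia" = 0.1), g3))
  expect_false(sociological_presence(c("isolepis setacea" = 0.2), g3))
  g4 <- species_group("G4", "SOC", c("A a", "B b", "C c", "D d"))
  expect_true(sociological_presence(c("a a" = 0.1, "c c" = 0.1), g4))
  expect_false(sociological_presence(c("a a" = 0.1), g4))
  # per-call override
  expect_true(sociological_presence(c("a a" = 0.1), g4, min_members = 1))
})

test_that("the formula parser builds the expected expression trees", {
  g <- tiny_groups()
  d <- parse_definition("TC(Mud) > 25 AND SOC(Rush)", g)
  expect_s3_class(d, "cocktail_definition")
  expect_equal(d$op, "and")
  expect_length(d$args, 2L)
  expect_equal(d$args[[1]]$op, "tc")
  expect_equal(d$args[[2]]$op, "soc")
  d2 <- parse_definition("NOT (COV(Cyperus michelianus) >= 25)", g)
  expect_equal(d2$op, "not")
  expect_equal(d2$args[[1]]$op, "cov")
  expect_equal(d2$args[[1]]$cmp, ">=")
  # operator precedence: AND binds tighter than OR
  d3 <- parse_definition("SOC(Rush) OR SOC(Rush) AND TC(Mud) > 5", g)
  expect_equal(d3$op, "or")
  expect_equal(d3$args[[2]]$op, "and")
  expect_error(parse_definition("TC(Nonexistent) > 5", g), "unknown")
  expect_error(parse_definition("TC(Mud) >", g), "number")
  expect_error(parse_definition("TC(Mud) > 5 extra", g), "syntax")
  expect_error(parse_definition("SC(Mud) > 5", g), "kind")
  expect_error(parse_definition("TC(Mud) > 500", g), "\\[0, 100\\]")
  # formatting round-trips through the parser
  expect_equal(format(parse_definition(format(d), g)), format(d))
})

test_that("evaluation follows boolean semantics over conditions", {
  g <- tiny_groups()
  cov <- c("cyperus fuscus" = 0.5, "limosella aquatica" = 0.5)
  expect_true(evaluate(parse_definition("TC(Mud) > 25", g), cov))
  expect_false(evaluate(parse_definition("TC(Mud) > 75", g), cov))  # strict
  expect_true(evaluate(parse_definition("TC(Mud) >= 75", g), cov))
  expect_false(evaluate(parse_definition("NOT TC(Mud) > 25", g), cov))
  expect_true(evaluate(parse_definition(
    "TC(Mud) > 80 OR SC(Peak) > 40", g), cov))
})

test_that("a full association formula matches an independent hand evaluation", {
  g <- load_packaged_groups()
  d <- parse_definition(
    "TC(Eleocharition soloniensis) > 10 AND SOC(Cyperus fuscus)", g)
  # relevé: C. fuscus 30 %, Potentilla supina 5 %, J. bufonius 10 %.
  cov <- c("cyperus fuscus" = 0.30, "potentilla supina" = 0.05,
           "juncus bufonius" = 0.10)
  # by hand: TC = 100 * (1 - 0.7 * 0.95) = 33.5 > 10; SOC has 2 of 3
  expect_equal(total_cover(cov, g[["Eleocharition soloniensis"]]),
               100 * (1 - 0.7 * 0.95))
  expect_true(evaluate(d, cov))
  # drop Potentilla: SOC has 1 of 3 members -> FALSE
  expect_false(evaluate(d, cov[-2]))
})

test_that("evaluation is pure and order-invariant", {
  g <- load_packaged_groups()
  h <- load_packaged_hierarchy()
  set.seed(42)
  univ <- unique(unlist(lapply(g, `[[`, "norm_members")))
  for (i in 1:25) {
    cov <- stats::setNames(runif(12, 0.01, 0.9), sample(univ, 12))
    r1 <- classify(cov, h)
    r2 <- classify(sample(cov), h)
    expect_identical(r1, r2)
  }
})

test_that("unequivocal classification assigns ancestors with the unit", {
  h <- load_packaged_hierarchy()
  cov <- c("cyperus fuscus" = 0.40, "potentilla supina" = 0.10,
           "limosella aquatica" = 0.15)
  r <- classify(cov, h)
  expect_equal(r$association, "Cypero fusci-Limoselletum aquaticae")
  expect_equal(r$alliance, "Eleocharition soloniensis")
  expect_equal(r$class, "Isoeto-Nanojuncetea")
  expect_false(r$conflict)
})

test_that("multi-match releves fall back to the deepest unique rank", {
  h <- load_packaged_hierarchy()
  # satisfies both Cypero-Limoselletum (SOC Cyperus fuscus) and
  # Polygono-Eleocharitetum (SOC Eleocharis ovata), same alliance
  cov <- c("cyperus fuscus" = 0.4, "limosella aquatica" = 0.2,
           "eleocharis ovata" = 0.4, "carex bohemica" = 0.2)
  r <- classify(cov, h)
  expect_true(r$conflict)
  expect_length(r$conflict_nodes, 2L)
  expect_true(is.na(r$association))
  expect_equal(r$alliance, "Eleocharition soloniensis")
  expect_equal(r$class, "Isoeto-Nanojuncetea")
})

test_that("releves matching nothing stay unassigned at every rank", {
  h <- load_packaged_hierarchy()
  r <- classify(c("quercus robur" = 0.8), h)
  expect_true(is.na(r$class) && is.na(r$alliance) && is.na(r$association))
  expect_false(r$conflict)
})

test_that("classify_table summarises per node and per level", {
  h <- load_packaged_hierarchy()
  # empty table
  empty <- classify_table(releve_table(), h)
  expect_equal(nrow(empty), 0L)
  # class-only plots: enough class-group species, no alliance group fires
  rec <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(plot_id = paste0("c", i),
               taxon = c("Juncus bufonius", "Gnaphalium uliginosum"),
               layer = "herb", cover = c(0.10, 0.10),
               stringsAsFactors = FALSE)
  }))
  res <- classify_table(releve_table(rec), h)
  s <- attr(res, "summary")
  expect_equal(unname(s$levels["class_only"]), 4L)
  expect_equal(unname(s$levels["association_level"]), 0L)
  expect_equal(sum(s$per_node$n[s$per_node$rank == "class"]), 4L)
})

test_that("assigned ranks always form a root-anchored path", {
  h <- load_packaged_hierarchy()
  ds <- generate_releves(n_per_unit = 10, seed = 9)
  res <- classify_table(ds$table, h)
  expect_true(all(is.na(res$association) | !is.na(res$alliance)))
  expect_true(all(is.na(res$alliance) | !is.na(res$class)))
  # association's recorded alliance is its true parent
  hit <- !is.na(res$association)
  parents <- vapply(res$association[hit],
                    function(a) h$nodes[[a]]$parent, character(1))
  expect_equal(unname(parents), res$alliance[hit])
})

test_that("hierarchy validation rejects malformed trees", {
  g <- tiny_groups()
  node <- function(name, rank, parent = NULL)
    list(name = name, rank = rank, parent = parent, formula = "SOC(Rush)")
  expect_error(syntaxon_hierarchy(list(node("A", "alliance")), g), "class")
  expect_error(syntaxon_hierarchy(
    list(node("C", "class"), node("A", "association", "C")), g),
    "alliance parent")
  expect_error(syntaxon_hierarchy(
    list(node("C", "class"), node("C2", "class")), g), "exactly one")
})
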
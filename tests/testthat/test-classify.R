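ruleset_fixture <- function() {
  parse_ruleset(data.frame(
    order = 1:3,
    expression = c("arr > 50 AND climbers < 5",
                   "holcus > 30 OR (festuca > 20 AND lolium < 10)",
                   "arr > 20"),
    type_id = c("tall_herb", "wet_meadow", "mixed"),
    stringsAsFactors = FALSE), default_type = "other")
}

test_that("rule expressions parse into condition trees", {
  rs <- ruleset_fixture()
  expect_length(rs$rules, 3)
  expect_equal(rs$rules[[1]]$expr$op, "AND")
  expect_equal(rs$rules[[1]]$expr$lhs$species, "arr")
  expect_error(parse_ruleset(data.frame(order = integer(0),
                                        expression = character(0),
                                        type_id = character(0)), "d"),
               "empty")
  expect_error(parse_ruleset(data.frame(order = c(1, 1),
                                        expression = c("a > 1", "a > 2"),
                                        type_id = c("x", "y")), "d"),
               "duplicate")
  expect_error(parse_ruleset(data.frame(order = 1, expression = "a >",
                                        type_id = "x"), "d"), "threshold")
  expect_error(parse_ruleset(data.frame(order = 1, expression = "a > 50",
                                        type_id = "x"), "d",
                             species_ids = "b"), "unknown species")
})

test_that("classification is first-match with strict comparators", {
  rs <- ruleset_fixture()
  expect_equal(classify_cover(c(arr = 60, climbers = 1), rs), "tall_herb")
  # a later rule also matches but the first wins
  expect_equal(classify_cover(c(arr = 60, climbers = 1, holcus = 40), rs),
               "tall_herb")
  expect_equal(classify_cover(c(arr = 50, climbers = 1), rs), "mixed")
  expect_equal(classify_cover(c(arr = 20), rs), "other")   # strict >
  expect_equal(classify_cover(numeric(0), rs), "other")
  expect_equal(classify_cover(c(festuca = 25, lolium = 5), rs), "wet_meadow")
})

test_that("rulesets round-trip through their table form", {
  rs <- ruleset_fixture()
  tab <- format_ruleset(rs)
  rs2 <- parse_ruleset(tab, default_type = rs$default_type)
  set.seed(11)
  for (i in 1:100) {
    cov <- stats::setNames(runif(5, 0, 80),
                           c("arr", "climbers", "holcus", "festuca", "lolium"))
    expect_equal(classify_cover(cov, rs2), classify_cover(cov, rs))
  }
})

test_that("reordering non-overlapping rules leaves classifications unchanged", {
  t1 <- data.frame(order = 1:2,
                   expression = c("a > 50", "b > 50"),
                   type_id = c("A", "B"), stringsAsFactors = FALSE)
  t2 <- t1[2:1, ]; t2$order <- 1:2
  r1 <- parse_ruleset(t1, "none"); r2 <- parse_ruleset(t2, "none")
  set.seed(12)
  for (i in 1:100) {
    cov <- c(a = runif(1, 0, 100), b = 100 - runif(1, 0, 100))
    cov["b"] <- min(cov["b"], 100 - cov["a"])  # covers cannot both exceed 50
    expect_equal(classify_cover(cov, r1), classify_cover(cov, r2))
  }
})

test_that("grid classification refreshes modeled cells only", {
  sp <- species_table(data.frame(species_id = c("a", "b"), name = c("A", "B"),
                                 L = 5, T = 5, M = 5, R = 5, N = 5,
                                 C = 5, G = 5, TR = 5, g_max = 4, f_s = 500))
  grid <- tiny_grid(sp, c(a = 60, b = 10), n_rows = 2, n_cols = 2)
  rs <- parse_ruleset(data.frame(order = 1, expression = "a > 50",
                                 type_id = "dom_a"), "other")
  g2 <- classify_grid(grid, rs)
  expect_true(all(g2$veg_type[g2$modeled] == "dom_a"))
})
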
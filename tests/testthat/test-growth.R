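test_that("mortality removes the annual rate divided over the steps", {
  expect_equal(mortality_step(0, 365), list(cover = 0, freed = 0))
  m <- mortality_step(50, 365)
  expect_equal(m$freed, 50 * 2 / 365)
  m <- mortality_step(52, 52)
  expect_equal(m$freed, 2)
  expect_equal(m$cover + m$freed, 52)
})

test_that("land-use control is linear, bounded on [1/9, 1]", {
  expect_equal(landuse_control(5, 0), 1)
  expect_equal(landuse_control(9, 100), 1)
  expect_equal(landuse_control(1, 100), 1 / 9)
  # full domain sweep stays inside the bounds
  grid <- expand.grid(eiv = seq(1, 9, by = 0.5), i = seq(0, 100, by = 5))
  f <- landuse_control(grid$eiv, grid$i)
  expect_true(all(f >= 1 / 9 - 1e-12 & f <= 1 + 1e-12))
  # decreasing in intensity below tolerance 9
  expect_true(all(diff(landuse_control(4, 0:100)) < 0))
  expect_error(landuse_control(NA, 50), "indifferent")
  expect_error(landuse_control(10, 50), "out of")
})

test_that("site control peaks at the species optimum and decays symmetrically", {
  expect_equal(site_control(7, 7, slope = 2), 1)
  expect_equal(site_control(5, 8, slope = 1), exp(-1))
  expect_equal(site_control(3, 6, 1), site_control(9, 6, 1))
  sv <- seq(1, 9, by = 0.25)
  f <- site_control(6, sv, slope = 1)
  expect_true(all(f > 0 & f <= 1))
  expect_true(which.max(f) == which(sv == 6))
  expect_true(all(diff(f[sv >= 6]) < 0))      # strictly decreasing beyond
  # indifferent species: reduced curve centred on the scale midpoint
  expect_equal(site_control(NA, 5, 1, slope_red = 0.3, opt_red = 0.6), 0.6)
  expect_equal(site_control(NA, 8, 1, slope_red = 0.3, opt_red = 0.6),
               0.6 * exp(-0.3 * 9 / 9))
  expect_error(site_control(5, 0, 1), "out of")
})

test_that("factor weighting inflates suboptimal factors", {
  expect_equal(factor_weight(1, 5), 1)
  expect_equal(factor_weight(0.5, 2), 2.25)
  expect_equal(factor_weight(0.5, 1), 1.5)
  f <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(factor_weight(f, 3)) < 0))
  expect_true(all(factor_weight(f, 4) <= 2^4))
})

test_that("total dependency is a weighted mean sandwiched by its factors", {
  expect_equal(total_dependency(c(a = 1, b = 1, c = 1), 1), 1)
  expect_equal(total_dependency(c(x = 0.7), 5), 0.7)
  expect_equal(total_dependency(c(1, 0.5), c(1, 1)),
               (1 * 1 + 1.5 * 0.5) / (1 + 1.5))
  set.seed(42)
  for (i in 1:50) {
    f <- runif(8, 0.05, 1)
    w <- sample(1:20, 8, replace = TRUE)
    ft <- total_dependency(f, w)
    expect_gte(ft, min(f))
    expect_lte(ft, max(f))
  }
  expect_error(total_dependency(numeric(0), numeric(0)), "empty")
})

test_that("growth rate is self-regulated and floored at zero", {
  expect_equal(growth_rate(1000, 5, 1000, 1), 0)
  expect_equal(growth_rate(10, 5, 1000, 1), 5 * 0.99)
  expect_equal(growth_rate(10, 5, 1000, 0.5), 0.5 * growth_rate(10, 5, 1000, 1))
  # cover above f_s: clamped, not negative
  expect_equal(growth_rate(80, 4, 50, 1), 0)
  expect_error(growth_rate(10, 4, 0, 1), "positive")
})

test_that("potential growth scales the annual rate by the step length", {
  expect_equal(potential_growth(3.65, 10, 365), 0.1)
  expect_equal(potential_growth(0, 10, 52), 0)
  expect_equal(potential_growth(2, 0, 52), 0)
})

test_that("space allocation is proportional under scarcity", {
  expect_equal(allocate_space(c(a = 1, b = 2), 10), c(a = 1, b = 2))
  expect_equal(allocate_space(c(a = 6, b = 2), 4), c(a = 3, b = 1))
  expect_equal(allocate_space(c(a = 0, b = 0), 4), c(a = 0, b = 0))
  set.seed(7)
  for (i in 1:50) {
    pot <- runif(5, 0, 3)
    as_ <- runif(1, 0, 5)
    real <- allocate_space(pot, as_)
    expect_equal(sum(real), min(sum(pot), as_), tolerance = 1e-9)
    # scaling all potentials leaves realized growth unchanged under scarcity
    if (sum(pot) > as_)
      expect_equal(allocate_space(2 * pot, as_), real, tolerance = 1e-12)
  }
  expect_error(allocate_space(c(-1, 2), 5), "negative")
})
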
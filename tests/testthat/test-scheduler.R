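test_that("an empty landscape stays empty", {
  sp <- tiny_species(2)
  grid <- tiny_grid(sp, c(sp1 = 0, sp2 = 0), n_rows = 3, n_cols = 3)
  run <- run_simulation(grid, years = 2)
  expect_true(all(run$grid$cover == 0))
})

test_that("the engine reproduces the single-species reference recursion", {
  sp <- tiny_species(1, g_max = 4, f_s = 500)
  grid <- tiny_grid(sp, c(sp1 = 5))      # matched site -> f_total = 1
  expect_equal(grid$f_total[1, 1], 1)
  run <- run_simulation(grid, years = 10, record_every = 1)
  eng <- vapply(run$records, function(r) r$cover[1, 1], numeric(1))
  ora <- single_species_trajectory(4, 500, 1, 5, 520, 52)[-1]
  expect_equal(eng, ora, tolerance = 1e-9)
})

test_that("two identical species stay identical without dispersal", {
  sp <- tiny_species(2, g_max = 4, f_s = 300)
  grid <- tiny_grid(sp, c(sp1 = 10, sp2 = 10))
  run <- run_simulation(grid, years = 5, record_every = 1)
  for (r in run$records)
    expect_equal(unname(r$cover[1, 1]), unname(r$cover[1, 2]))
})

test_that("area is conserved in every cell after every step", {
  sp <- tiny_species(4, g_max = c(3, 4, 5, 6), f_s = c(100, 300, 500, 1000))
  init <- c(sp1 = 30, sp2 = 30, sp3 = 20, sp4 = 15)
  grid <- tiny_grid(sp, init, n_rows = 4, n_cols = 4,
                    dispersal_threshold = 1)
  run <- simulation_run(grid, record_every = 1)
  set.seed(5)
  for (t in 1:120) {
    run <- simulation_step(run)
    tot <- rowSums(run$grid$cover)[run$grid$modeled]
    avail <- 100 - tot
    expect_true(all(avail >= -1e-6))
    expect_true(all(tot + avail - 100 < 1e-6))   # identity by construction
    expect_true(all(run$grid$cover >= 0))
  }
})

test_that("equilibrium trajectories are quasi-invariant to the step size", {
  # off equilibrium the linear per-step mortality/growth split compounds
  # first-order differences between 52 and 365 steps; once the transient has
  # passed, yearly values agree within discretisation error (< 2 %)
  t52 <- single_species_trajectory(4, 500, 0.9, 5, 52 * 10, 52)
  t365 <- single_species_trajectory(4, 500, 0.9, 5, 365 * 10, 365)
  y52 <- t52[1 + 52 * (5:10)]
  y365 <- t365[1 + 365 * (5:10)]
  expect_true(all(abs(y52 - y365) / y365 < 0.02))
  sp <- tiny_species(1, g_max = 4, f_s = 500)
  gw <- tiny_grid(sp, c(sp1 = 5), steps_per_year = 52)
  gd <- tiny_grid(sp, c(sp1 = 5), steps_per_year = 365)
  rw <- landscape_mean_cover(run_simulation(gw, years = 8, record_every = 52))
  rd <- landscape_mean_cover(run_simulation(gd, years = 8,
                                            record_every = 365))
  wend <- rw$sp1[rw$step == 52][5:8]
  dend <- rd$sp1[rd$step == 365][5:8]
  expect_true(all(abs(wend - dend) / dend < 0.02))
})

test_that("without dispersal, cells evolve independently", {
  sp <- tiny_species(2, g_max = c(4, 5), f_s = c(200, 400))
  init <- c(sp1 = 10, sp2 = 20)
  g1 <- tiny_grid(sp, init, n_rows = 1, n_cols = 1)
  gN <- tiny_grid(sp, init, n_rows = 3, n_cols = 3)
  r1 <- run_simulation(g1, years = 4)
  rN <- run_simulation(gN, years = 4)
  last1 <- r1$records[[length(r1$records)]]$cover
  lastN <- rN$records[[length(rN$records)]]$cover
  for (cell in 1:9) expect_equal(unname(lastN[cell, ]), unname(last1[1, ]))
})

test_that("unmodeled cells never change", {
  sp <- tiny_species(1, g_max = 6, f_s = 5000)
  vt <- vegtype_table(
    data.frame(type_id = c("veg", "rock"), name = c("V", "R"),
               simulated = c(TRUE, FALSE), stringsAsFactors = FALSE),
    initial_cover = list(veg = c(sp1 = 50)))
  tm <- matrix("veg", 4, 4); tm[2, 2] <- "rock"
  g <- global_params(n_years = 2, dispersal_threshold_pct = 1, rng_seed = 1)
  grid <- build_grid(tm, rep(list(matrix(5, 4, 4)), 5),
                     rep(list(matrix(0, 4, 4)), 3), vt, sp, g)
  run <- run_simulation(grid, years = 2)
  rock <- (2 - 1) * 4 + 2
  expect_equal(unname(run$grid$cover[rock, ]), 0)
  expect_equal(run$grid$veg_type[rock], "rock")
})

test_that("recorder cadence beyond the horizon yields an empty table", {
  sp <- tiny_species(1)
  grid <- tiny_grid(sp, c(sp1 = 5))
  run <- run_simulation(grid, years = 1, record_every = 1000)
  lm <- landscape_mean_cover(run)
  expect_equal(nrow(lm), 0)
  expect_named(lm, c("year", "step", "sp1"))
})
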
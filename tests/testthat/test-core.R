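test_that("species table validation enforces ranges and uniqueness", {
  df <- as.data.frame(tiny_species(3))
  expect_s3_class(species_table(df), "species_table")
  bad <- df; bad$species_id[2] <- "sp1"
  expect_error(species_table(bad), "duplicate")
  bad <- df; bad$C[1] <- NA
  expect_error(species_table(bad), "land-use")
  bad <- df; bad$g_max[1] <- 12
  expect_error(species_table(bad), "g_max")
  bad <- df; bad$L[3] <- 9.5
  expect_error(species_table(bad), "out of \\[1,9\\]")
  ok <- df; ok$L[1] <- NA; ok$M[2] <- 4.5   # indifferent + fractional allowed
  expect_s3_class(species_table(ok), "species_table")
})

test_that("global parameters validate their documented ranges", {
  g <- global_params()
  expect_equal(unname(g$weights["N"]), 1)
  expect_error(global_params(steps_per_year = 12), "52 or 365")
  expect_error(global_params(weights = 25), "out of")
  expect_error(global_params(slope_red = 1.5), "out of")
  g2 <- global_params(slope = c(L = 2, T = 1, M = 1, R = 0.5, N = 1))
  expect_equal(unname(g2$slope["R"]), 0.5)
})

test_that("grid construction initialises covers from the vegetation type", {
  sp <- tiny_species(2)
  vt <- vegtype_table(
    data.frame(type_id = c("a", "b", "road"), name = c("A", "B", "Road"),
               simulated = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE),
    initial_cover = list(a = c(sp1 = 30, sp2 = 10), b = c(sp1 = 5)))
  tm <- matrix(c("a", "b", "road", "a"), 2, 2)
  g <- global_params(n_years = 1)
  site <- rep(list(matrix(5, 2, 2)), 5)
  lu <- rep(list(matrix(0, 2, 2)), 3)
  grid <- build_grid(tm, site, lu, vt, sp, g)
  # row-major indexing: tm[1,1]="a" -> cell 1; tm[1,2]="road" -> cell 2
  expect_equal(unname(grid$cover[1, ]), c(30, 10))
  expect_false(grid$modeled[2])
  expect_equal(unname(grid$cover[2, ]), c(0, 0))
  expect_equal(unname(grid$cover[3, ]), c(5, 0))    # tm[2,1]="b"
  expect_true(all(grid$ingrowth_current == 0) && all(grid$ingrowth_next == 0))
  # rebuilding yields identical state
  expect_identical(grid$cover,
                   build_grid(tm, site, lu, vt, sp, g)$cover)
  expect_error(build_grid(matrix("zz", 2, 2), site, lu, vt, sp, g),
               "unknown vegetation type")
  expect_error(build_grid(tm, rep(list(matrix(5, 3, 2)), 5), lu, vt, sp, g),
               "dimensions")
})

test_that("Moore neighbourhood respects the closed boundary", {
  sp <- tiny_species(1)
  grid <- tiny_grid(sp, c(sp1 = 1), n_rows = 10, n_cols = 10)
  expect_equal(nrow(neighbors8(grid, 1, 1)), 3)
  expect_equal(nrow(neighbors8(grid, 5, 5)), 8)
  nb <- neighbors8(grid, 1, 5)
  expect_equal(nrow(nb), 5)
  expect_setequal(paste(nb[, 1], nb[, 2]),
                  c("1 4", "1 6", "2 4", "2 5", "2 6"))
  expect_error(neighbors8(grid, 0, 5), "out of bounds")
  # symmetry: b in N(a) <=> a in N(b)
  for (i in 1:20) {
    r <- sample(10, 1); cl <- sample(10, 1)
    nb <- neighbors8(grid, r, cl)
    for (j in seq_len(nrow(nb))) {
      back <- neighbors8(grid, nb[j, 1], nb[j, 2])
      expect_true(any(back[, 1] == r & back[, 2] == cl))
    }
  }
})

test_that("seed bank initialisation gives every species a foothold", {
  sp <- tiny_species(11)
  grid <- tiny_grid(sp, stats::setNames(rep(0, 11), sp$species_id),
                    n_rows = 3, n_cols = 3)
  g2 <- seed_bank_initialize(grid, 1)
  expect_true(all(rowSums(g2$cover)[g2$modeled] == 11))
  sp17 <- tiny_species(17)
  grid17 <- tiny_grid(sp17, stats::setNames(rep(0, 17), sp17$species_id))
  expect_equal(sum(seed_bank_initialize(grid17, 0.1)$cover[1, ]), 1.7)
  expect_error(seed_bank_initialize(grid17, 7), "exceed|above 100")
})
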
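releve_species <- function() {
  species_table(data.frame(
    species_id = c("a", "b", "c"),
    name = c("A", "B", "C"),
    L = c(7, 5, 6), T = 5, M = c(3, 5, 9), R = c(7, NA, 6), N = 5,
    C = 5, G = 5, TR = 5, g_max = 4, f_s = 500, stringsAsFactors = FALSE))
}

test_that("releve aggregation supports median, mean and cover weighting", {
  sp <- releve_species()
  rel <- data.frame(species_id = c("a", "b", "c"), cover = c(50, 25, 25))
  expect_equal(mean_site_eiv(rel, sp, "L", "mean"), 6)
  expect_equal(mean_site_eiv(rel, sp, "L", "cover_weighted_mean"), 6.25)
  expect_equal(mean_site_eiv(rel, sp, "M", "median"), 5)
  # indifferent species are skipped
  expect_equal(mean_site_eiv(rel, sp, "R", "mean"), 6.5)
  only_b <- data.frame(species_id = "b", cover = 10)
  expect_error(mean_site_eiv(only_b, sp, "R"), "non-indifferent")
  expect_error(mean_site_eiv(data.frame(species_id = "zz", cover = 1), sp,
                             "L"), "not in the species table")
})

test_that("soil attributes map onto the documented indicator classes", {
  expect_equal(as.numeric(soil_to_site_eiv(list(moisture_class = "wet"), "M")),
               8.5)
  expect_equal(attr(soil_to_site_eiv(list(moisture_class = "wet"), "M"),
                    "range"), c(8, 9))
  expect_equal(as.numeric(soil_to_site_eiv(list(cec_class = "<40"), "R")), 2)
  expect_equal(as.numeric(soil_to_site_eiv(list(cec_class = ">640"), "R")), 9)
  # altitude classes: 650-450 m band carries value 5
  expect_equal(soil_to_site_eiv(list(altitude_m = 500), "T"), 5)
  expect_equal(soil_to_site_eiv(list(altitude_m = 350), "T"), 6)
  expect_equal(soil_to_site_eiv(list(altitude_m = 100), "T"), 7)
  warm <- soil_to_site_eiv(list(altitude_m = -1), "T")
  expect_true(is.na(warm) && isTRUE(attr(warm, "undetermined")))
  # nutrient value from soil type / texture / topsoil thickness
  expect_equal(as.numeric(soil_to_site_eiv(list(soil_type = "P"), "N")), 2)
  expect_equal(soil_to_site_eiv(list(soil_type = "R"), "N"), 3)
  expect_equal(as.numeric(soil_to_site_eiv(
    list(soil_type = "B", texture_class = 6), "N")), 3.5)
  expect_equal(as.numeric(soil_to_site_eiv(
    list(soil_type = "G", texture_class = 3, topsoil_thickness = "<60"),
    "N")), 5)
  expect_equal(as.numeric(soil_to_site_eiv(
    list(soil_type = "L", texture_class = 2, topsoil_thickness = "60-200"),
    "N")), 6.5)
  expect_equal(as.numeric(soil_to_site_eiv(
    list(soil_type = "K", texture_class = 1, topsoil_thickness = ">200"),
    "N")), 8.5)
  # light: covered sites cannot be resolved without more information
  shaded <- soil_to_site_eiv(list(covered = TRUE), "L")
  expect_true(is.na(shaded) && isTRUE(attr(shaded, "undetermined")))
  expect_equal(as.numeric(soil_to_site_eiv(
    list(open_area_m2 = 10000, aspect = "SE-SW", hillslope = "5-20"), "L")),
    9)
  expect_equal(as.numeric(soil_to_site_eiv(
    list(open_area_m2 = 1000, aspect = "WSW-ESE", hillslope = ">20"), "L")),
    6)
  expect_error(soil_to_site_eiv(list(), "M"), "missing soil attribute")
})

test_that("soil lookup is total over the controlled vocabularies", {
  aspects <- c("WSW-ESE", "SE-SW", "unspecified")
  slopes <- c("<5", "5-20", ">20", "unspecified")
  for (sz in c(1000, 10000)) for (a in aspects) for (s in slopes) {
    v <- soil_to_site_eiv(list(open_area_m2 = sz, aspect = a, hillslope = s),
                          "L")
    expect_true(is.na(v) || (v >= 1 && v <= 9))
  }
  soils <- c("P", "Q", "E", "O", "N", "R", "Z", "B", "L", "K", "S", "SG",
             "G", "GN")
  ths <- c("<60", "60-200", ">200")
  for (st in soils) for (tx in 1:9) for (th in ths) {
    v <- soil_to_site_eiv(list(soil_type = st, texture_class = tx,
                               topsoil_thickness = th), "N")
    expect_true(is.na(v) || (v >= 1 && v <= 9))
  }
})

test_that("land-use scenario catalogue returns the published triples", {
  expect_equal(scenario_intensities("Hay-meadow")$intensities,
               c(C = 75, G = 1, TR = 1))
  expect_equal(scenario_intensities("Intensive pasture")$intensities,
               c(C = 0, G = 50, TR = 50))
  expect_equal(scenario_intensities("Fallow")$intensities,
               c(C = 0, G = 1, TR = 1))
  expect_equal(scenario_intensities("Extensive pasture")$intensities,
               c(C = 0, G = 35, TR = 20))
  expect_error(scenario_intensities("Golf course"), "unknown")
})
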
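test_that("rendering is bit-identical under the same seed", {
  scn <- make_scenario("mmr_like", n_rows = 8, n_cols = 8,
                       years = 2001:2003, seed = 7)
  a <- render_series(scn, scenes_per_season = 2)
  b <- render_series(scn, scenes_per_season = 2)
  expect_identical(a, b)
})

test_that("the seed moves the noise but not the class map", {
  s1 <- make_scenario("mmr_like", n_rows = 8, n_cols = 8,
                      years = 2001:2002, seed = 1)
  s2 <- make_scenario("mmr_like", n_rows = 8, n_cols = 8,
                      years = 2001:2002, seed = 2)
  expect_identical(s1$class_map, s2$class_map)
  a <- render_series(s1, 1); b <- render_series(s2, 1)
  expect_false(identical(a$reflectance[[1]]$bands, b$reflectance[[1]]$bands))
})

test_that("the noiseless limit reproduces class signatures exactly", {
  scn <- make_scenario("mmr_like", n_rows = 6, n_cols = 6,
                       years = 2001:2002, noise_sd = 0, lst_noise_sd = 0,
                       cloud_fraction = 0, trend_spec = list(),
                       change_spec = NULL, thermal_coarse_factor = 1,
                       seed = 3)
  ser <- render_series(scn, 1)
  sig <- scn$signatures$reflectance
  sc <- ser$reflectance[[1]]
  for (cls in unique(as.vector(scn$class_map))) {
    cell <- which(scn$class_map == cls, arr.ind = TRUE)[1, ]
    expect_equal(sc$bands[cell[1], cell[2], ], sig[cls, ],
                 ignore_attr = TRUE)
  }
  # LST 26.85 C encodes as digital number 15000
  scn2 <- make_scenario("uniform", n_rows = 2, n_cols = 2, years = 2001,
                        noise_sd = 0, lst_noise_sd = 0, cloud_fraction = 0,
                        trend_spec = list(), change_spec = NULL,
                        thermal_coarse_factor = 1,
                        signatures = list(
                          reflectance = matrix(0.1, 1, 7,
                            dimnames = list("agriculture", band_roles)),
                          lst_c = c(agriculture = 26.85)), seed = 1)
  ser2 <- render_series(scn2, 1)
  expect_equal(ser2$thermal[[1]]$dn[1, 1], 15000)
})

test_that("linear drift accumulates exactly over the years", {
  tr <- list(agriculture = list(bands = c(0, 0.01, 0, 0, 0, 0, 0), lst = 0))
  scn <- make_scenario("uniform", n_rows = 3, n_cols = 3, years = 2001:2025,
                       noise_sd = 0, lst_noise_sd = 0, cloud_fraction = 0,
                       trend_spec = tr, change_spec = NULL,
                       thermal_coarse_factor = 1, seed = 1)
  ser <- render_series(scn, 1)
  first <- ser$reflectance[[which(ser$index_year == 2001)[1]]]
  last <- ser$reflectance[[which(ser$index_year == 2025)[1]]]
  expect_equal(last$bands[1, 1, "nir1"] - first$bands[1, 1, "nir1"], 0.24,
               ignore_attr = TRUE)
})

test_that("noise averages to the drifted signature at LLN precision", {
  scn <- make_scenario("uniform", n_rows = 20, n_cols = 20, years = 2001,
                       noise_sd = 0.05, lst_noise_sd = 0, cloud_fraction = 0,
                       trend_spec = list(), change_spec = NULL,
                       thermal_coarse_factor = 1, seed = 9)
  ser <- render_series(scn, 8)
  vals <- unlist(lapply(ser$reflectance, function(s) s$bands[, , "nir1"]))
  n <- length(vals)
  sig <- scn$signatures$reflectance["agriculture", "nir1"]
  expect_lt(abs(mean(vals) - sig), 3 * 0.05 / sqrt(n))
})

test_that("QA flag rate stays within 3 binomial sd of cloud_fraction", {
  p <- 0.2
  scn <- make_scenario("uniform", n_rows = 20, n_cols = 20, years = 2001:2002,
                       cloud_fraction = p, thermal_coarse_factor = 1,
                       trend_spec = list(), change_spec = NULL, seed = 4)
  ser <- render_series(scn, 4)
  flags <- unlist(ser$qa)
  n <- length(flags)
  expect_lt(abs(mean(flags) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("truth layers describe the injected structure", {
  scn0 <- make_scenario("uniform", n_rows = 5, n_cols = 5, years = 2001:2010,
                        trend_spec = list(), change_spec = NULL, seed = 1)
  tl0 <- truth_layers(scn0)
  expect_true(all(tl0$trend_sign == 0))
  expect_true(all(is.na(tl0$change_year)))
  expect_equal(sum(tl0$region), 0)

  region <- matrix(FALSE, 5, 5); region[1:2, 1:3] <- TRUE
  scn1 <- make_scenario("uniform", n_rows = 5, n_cols = 5, years = 2001:2010,
                        trend_spec = list(agriculture = list(
                          bands = c(0, 0.01, 0, 0, 0, 0, 0), lst = 0)),
                        change_spec = list(region = region,
                                           change_year = 2007L,
                                           bands = rep(0.1, 7), lst = 0),
                        seed = 1)
  tl1 <- truth_layers(scn1)
  expect_true(all(tl1$trend_sign == 1))  # NIR1 drift raises NDVI
  expect_equal(sum(tl1$region), 6)
  expect_equal(sum(tl1$change_year == 2007L, na.rm = TRUE), 6)
})

test_that("the annual-index cube encodes drift, step and truth consistently", {
  ic <- make_index_cube(n_rows = 6, n_cols = 6, years = 2001:2010,
                        base = 0.4, drift = 0.02, step = 0.1,
                        change_year = 2007L, noise_sd = 0, seed = 1)
  expect_identical(ic, make_index_cube(n_rows = 6, n_cols = 6,
                                       years = 2001:2010, base = 0.4,
                                       drift = 0.02, step = 0.1,
                                       change_year = 2007L, noise_sd = 0,
                                       seed = 1))
  drifted <- which(ic$truth$drift_region, arr.ind = TRUE)[1, ]
  still <- which(!ic$truth$drift_region, arr.ind = TRUE)[1, ]
  series <- ic$cube[drifted[1], drifted[2], ]
  expect_equal(series[10] - series[1], 0.02 * 9 + 0.1)
  expect_true(all(ic$cube[still[1], still[2], ] == 0.4))
  expect_equal(ic$truth$change_year[drifted[1], drifted[2]], 2007L)
})
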
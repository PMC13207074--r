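test_that("geo_grid validates its fields and reports cell centers", {
  g <- geo_grid(10, 8, 0.005, -36.1, -9.3)
  expect_equal(g$n_rows, 10L)
  ctr <- cell_centers(g)
  expect_equal(ctr$lon[1], -36.1 + 0.0025)
  expect_equal(ctr$lat[1], -9.3 - 0.0025)
  expect_equal(diff(ctr$lat)[1], -0.005)  # rows run north to south
  expect_error(geo_grid(0, 5, 0.005, 0, 0), "n_rows")
  expect_error(geo_grid(5, 5, -1, 0, 0), "cell_size_deg")
})

test_that("GeoTIFF round trip preserves values, nodata, grid and metadata", {
  g <- tiny_grid(10, 10)
  set.seed(7)
  x <- array(runif(10 * 10 * 7), dim = c(10, 10, 7))
  x[3, 4, ] <- NA
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(x, g, f, "float32",
                description = list(acq_date = "2001-01-09"))
  r <- read_geotiff(f)
  expect_true(grids_equal(r$grid, g))
  expect_equal(r$n_bands, 7L)
  expect_equal(r$grid$cell_size_deg, 0.005)
  expect_lt(max(abs(r$values - x), na.rm = TRUE), 1e-6)  # float32 storage
  expect_true(all(is.na(r$values[3, 4, ])))
  expect_equal(r$description$acq_date, "2001-01-09")

  xi <- matrix(c(1:19, NA), 4, 5)
  fi <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(xi, tiny_grid(4, 5), fi, "int32")
  ri <- read_geotiff(fi)
  expect_identical(ri$values[, , 1][1:19], as.numeric(1:19))
  expect_true(is.na(ri$values[4, 5, 1]))
})

test_that("codec agrees with an independent TIFF implementation", {
  # write with the package, verify with Python tifffile; then the reverse
  g <- tiny_grid(3, 4, cell = 0.01, lon = -36, lat = -9)
  x <- matrix(as.numeric(1:12) / 7, 3, 4)
  ours <- withr::local_tempfile(fileext = ".tif")
  theirs <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(x, g, ours, "float32")
  script <- sprintf(
    "import tifffile, numpy as np, sys\np = tifffile.TiffFile(%s).pages[0]\na = p.asarray()\nref = (np.arange(1, 13, dtype=np.float64) / 7).reshape(4, 3).T.astype(np.float32)\nassert a.shape == (3, 4), a.shape\nassert np.allclose(a, ref), a\nassert p.tags['ModelPixelScaleTag'].value[:2] == (0.01, 0.01)\nassert p.tags['ModelTiepointTag'].value[3:5] == (-36.0, -9.0)\ntifffile.imwrite(%s, ref * 2, extratags=[(33550, 'd', 3, (0.01, 0.01, 0.0)), (33922, 'd', 6, (0., 0., 0., -36., -9., 0.))])\nprint('OK')\n",
    deparse(ours), deparse(theirs))
  out <- system2("python", c("-c", shQuote(script)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(tail(out, 1), "OK")
  r <- read_geotiff(theirs)
  expect_true(grids_equal(r$grid, g))
  expect_lt(max(abs(r$values[, , 1] - 2 * x)), 1e-6)
})

test_that("read_scene echoes headers, applies scaling and checks bands", {
  g <- tiny_grid(10, 10)
  f <- withr::local_tempfile(fileext = ".tif")
  arr <- array(0.2, dim = c(10, 10, 7))
  write_geotiff(arr, g, f, "float32",
                description = list(acq_date = "2000-11-15",
                                   kind = "reflectance"))
  sc <- read_scene(f, "reflectance")
  expect_s3_class(sc, "reflectance_scene")
  expect_equal(sc$grid$n_rows, 10L)
  expect_equal(sc$grid$cell_size_deg, 0.005)
  expect_equal(sc$acq_date, as.Date("2000-11-15"))

  # scaled-integer storage (MOD09A1 convention): 5000 x 1e-4 -> 0.5
  fi <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(array(5000L, dim = c(10, 10, 7)), g, fi, "int32",
                description = list(acq_date = "2000-11-15",
                                   reflectance_scale = 1e-4))
  si <- read_scene(fi, "reflectance")
  expect_equal(si$bands[1, 1, "red"], 0.5, ignore_attr = TRUE)

  # band-count mismatch is a contract violation
  f6 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(array(0.2, dim = c(10, 10, 6)), g, f6, "float32",
                description = list(acq_date = "2000-11-15"))
  expect_error(read_scene(f6, "reflectance"), "7 band")
})

test_that("scene writers round-trip through their readers", {
  g <- tiny_grid(5, 6)
  sc <- flat_scene(g, date = "2003-12-01", nir1 = 0.44)
  sc$bands[2, 2, ] <- NA
  f <- withr::local_tempfile(fileext = ".tif")
  write_scene(sc, f)
  back <- read_scene(f, "reflectance")
  expect_equal(back$acq_date, sc$acq_date)
  expect_lt(max(abs(back$bands - sc$bands), na.rm = TRUE), 1e-6)
  expect_true(all(is.na(back$bands[2, 2, ])))

  th <- thermal_scene(g, "2003-12-01", matrix(15000, 5, 6))
  th$dn[1, 1] <- NA
  ft <- withr::local_tempfile(fileext = ".tif")
  write_scene(th, ft)
  backt <- read_scene(ft, "thermal")
  expect_equal(backt$dn[2, 2], 15000)
  expect_true(is.na(backt$dn[1, 1]))
})

test_that("quality masking applies bit tests and passes retained cells through", {
  g <- tiny_grid(2, 2)
  sc <- flat_scene(g, nir1 = 0.31)
  qa <- matrix(0L, 2, 2)

  # qa word 0 everywhere -> scene unchanged, bit-exact
  out <- apply_quality_mask(sc, qa, qa_bits_mod09a1())
  expect_identical(out$bands, sc$bands)

  # cloud-state bits 0-1 nonzero -> nodata
  qa[1, 1] <- 1L
  out <- apply_quality_mask(sc, qa, qa_bits_mod09a1())
  expect_true(all(is.na(out$bands[1, 1, ])))
  expect_identical(out$bands[2, 2, ], sc$bands[2, 2, ])

  # word 4: bits 0-1 = 0 (clear) but shadow bit 2 = 1 -> nodata
  qa <- matrix(c(4L, 0L, 0L, 0L), 2, 2)
  out <- apply_quality_mask(sc, qa, qa_bits_mod09a1())
  expect_true(all(is.na(out$bands[1, 1, ])))
  expect_false(anyNA(out$bands[2, 1, ]))
  # under a cloud-only spec the same word passes
  out2 <- apply_quality_mask(sc, qa,
                             list(cloud = list(bits = c(0L, 1L), ok = 0L)))
  expect_false(anyNA(out2$bands[1, 1, ]))

  # NA quality words drop the cell; grid mismatch errors
  qa_na <- matrix(c(NA, 0L, 0L, 0L), 2, 2)
  expect_true(all(is.na(apply_quality_mask(sc, qa_na)$bands[1, 1, ])))
  expect_error(apply_quality_mask(sc, matrix(0L, 3, 3)), "dimensions")

  # thermal scenes mask the same way
  th <- flat_thermal(g)
  qa <- matrix(c(3L, 0L, 0L, 0L), 2, 2)
  expect_true(is.na(apply_quality_mask(th, qa)$dn[1, 1]))
})
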
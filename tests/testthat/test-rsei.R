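test_that("min-max normalization maps valid cells onto [0, 1]", {
  expect_equal(normalize_indicator(matrix(c(2, 4, 6), 1)),
               matrix(c(0, 0.5, 1), 1))
  # masked cells are ignored when finding the extremes
  x <- matrix(c(0.2, 0.4, 0.8), 1)
  mask <- matrix(c(FALSE, TRUE, TRUE), 1)
  out <- normalize_indicator(x, mask)
  expect_true(is.na(out[1, 1]))
  expect_equal(out[1, 2:3], c(0, 1))
  expect_error(normalize_indicator(matrix(1, 2, 2)), "degenerate|constant")
})

test_that("perfectly collinear indicators put all variance on PC1", {
  set.seed(13)
  g <- matrix(runif(25), 5, 5)
  st <- make_stack(dryness = 1 - g, greenness = g, heat = 1 - g, wetness = g)
  layer <- compute_rsei(st)
  expect_equal(layer$pca$explained_fraction[1], 1)
})

test_that("PC1 agrees with an explicit-summation eigen oracle", {
  set.seed(17)
  d <- matrix(runif(64), 8); g <- matrix(runif(64), 8)
  h <- matrix(runif(64), 8); w <- matrix(runif(64), 8)
  st <- make_stack(dryness = d, greenness = g, heat = h, wetness = w)
  layer <- compute_rsei(st)
  x <- cbind(st$dryness_n[st$valid_mask], st$greenness_n[st$valid_mask],
             st$heat_n[st$valid_mask], st$wetness_n[st$valid_mask])
  orc <- oracle_pc1_loadings(x)
  lo <- unname(layer$pca$loadings)
  flip <- sign(lo[which.max(abs(lo))]) * sign(orc$loadings[which.max(abs(lo))])
  expect_lt(max(abs(lo - flip * orc$loadings)), 1e-8)
  expect_lt(max(abs(layer$pca$explained_fraction - orc$explained)), 1e-8)
  expect_equal(sum(layer$pca$explained_fraction), 1, tolerance = 1e-9)
})

test_that("orientation rule keeps RSEI aligned with greenness", {
  set.seed(19)
  for (seed in 1:4) {
    set.seed(seed)
    g <- matrix(runif(49), 7)
    # anti-correlated dryness/heat plus noise, the typical field structure
    st <- make_stack(dryness = 1 - g + matrix(rnorm(49, 0, 0.1), 7),
                     greenness = g,
                     heat = 1 - g + matrix(rnorm(49, 0, 0.1), 7),
                     wetness = g + matrix(rnorm(49, 0, 0.1), 7))
    layer <- compute_rsei(st)
    v <- layer$valid_mask
    expect_gt(cor(layer$rsein[v], st$greenness_n[v]), 0)
    expect_lte(cor(layer$rsein[v], st$dryness_n[v]), 0)
  }
})

test_that("RSEIn attains both 0 and 1 on every non-degenerate year", {
  set.seed(23)
  st <- make_stack(dryness = matrix(runif(36), 6),
                   greenness = matrix(runif(36), 6),
                   heat = matrix(runif(36), 6),
                   wetness = matrix(runif(36), 6))
  # independent indicators make the greenness/wetness loadings disagree,
  # which the orientation rule resolves (and flags) via greenness
  expect_warning(layer <- compute_rsei(st), "decided by the greenness")
  expect_equal(range(layer$rsein[layer$valid_mask]), c(0, 1))
})

test_that("too few valid cells is an error", {
  d <- matrix(NA_real_, 3, 3); d[1, 1:3] <- c(0.1, 0.5, 0.9)
  st <- try(make_stack(dryness = d, greenness = d, heat = d, wetness = d),
            silent = TRUE)
  if (!inherits(st, "try-error"))
    expect_error(compute_rsei(st), "valid cells")
})

test_that("five quality classes with upper-owned boundaries", {
  expect_equal(classify_rsei(0.1)[1], 1L)    # Poor
  expect_equal(classify_rsei(0.45)[1], 3L)   # Moderate
  expect_equal(classify_rsei(0.95)[1], 5L)   # Excellent
  expect_equal(classify_rsei(0.2)[1], 2L)    # boundary owned by Fair
  expect_equal(classify_rsei(1.0)[1], 5L)    # closed top endpoint
  expect_equal(classify_rsei(0)[1], 1L)
  cls <- classify_rsei(matrix(c(0.1, NA, 0.85, 0.6), 2, 2))
  expect_true(is.na(cls[2, 1]))
  expect_equal(attr(cls, "labels"), rsei_class_labels)
  expect_error(classify_rsei(1.2), "\\[0, 1\\]")
  expect_error(classify_rsei(-0.1), "\\[0, 1\\]")
})

test_that("annual statistics match hand arithmetic", {
  st <- annual_stats(matrix(c(0.4, 0.5, 0.6), 1), 2001)
  expect_equal(st$mean, 0.5)
  expect_equal(st$sd, 0.1)          # n-1 denominator
  expect_equal(st$cv, 20)
  expect_equal(st$median, 0.5)
  expect_equal(st$min, 0.4); expect_equal(st$max, 0.6)

  const <- annual_stats(matrix(0.3, 2, 2), 2002)
  expect_equal(const$sd, 0); expect_equal(const$cv, 0)

  set.seed(29)
  v <- matrix(runif(50), 5, 10)
  s <- annual_stats(v, 2003)
  expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$max)
  expect_equal(s$min, min(v)); expect_equal(s$max, max(v))
  expect_error(annual_stats(matrix(0.5, 1, 1), 2004), "2 valid")
})

test_that("urban cores score below dense vegetation on an mmr-like scene", {
  scn <- make_scenario("mmr_like", n_rows = 14, n_cols = 14, years = 2001,
                       cloud_fraction = 0.1, trend_spec = list(),
                       change_spec = NULL, seed = 31)
  ser <- render_series(scn, 3)
  refl <- lapply(seq_along(ser$reflectance), function(i)
    apply_quality_mask(ser$reflectance[[i]], ser$qa[[i]], qa_bits_single()))
  therm <- lapply(seq_along(ser$thermal), function(i) {
    s <- apply_quality_mask(ser$thermal[[i]], ser$qa_thermal[[i]],
                            qa_bits_single())
    resample_scene(s, scn$grid)
  })
  comp <- seasonal_composite(refl, therm, 2001L)
  layer <- compute_rsei(indicator_stack(comp))
  urban <- layer$rsein[scn$class_map == "urban" & layer$valid_mask]
  veg <- layer$rsein[scn$class_map == "dense_vegetation" & layer$valid_mask]
  expect_gt(length(urban), 5); expect_gt(length(veg), 5)
  expect_lt(mean(urban), mean(veg))
})
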
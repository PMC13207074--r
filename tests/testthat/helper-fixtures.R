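# Fixture builders and independent brute-force oracles.  The oracles use
# naive explicit enumeration so they stay independent of the implementation
# paths they check.

tiny_grid <- function(n_rows = 4L, n_cols = 4L, cell = 0.005,
                      lon = -36.1, lat = -9.3) {
  geo_grid(n_rows, n_cols, cell, lon, lat)
}

# composite with constant band values (named by role) and constant LST
make_composite <- function(values, lst_c = 25, n_rows = 3L, n_cols = 3L,
                           index_year = 2001L) {
  grid <- tiny_grid(n_rows, n_cols)
  bands <- array(NA_real_, dim = c(n_rows, n_cols, 7L),
                 dimnames = list(NULL, NULL, band_roles))
  for (role in band_roles) {
    v <- if (role %in% names(values)) values[[role]] else 0.1
    bands[, , role] <- if (is.matrix(v)) v else matrix(v, n_rows, n_cols)
  }
  lst <- if (is.matrix(lst_c)) lst_c else matrix(lst_c, n_rows, n_cols)
  valid <- !is.na(lst)
  for (b in seq_len(7L)) valid <- valid & !is.na(bands[, , b])
  structure(list(index_year = index_year, grid = grid, bands = bands,
                 lst_celsius = lst, valid_mask = valid),
            class = "annual_composite")
}

# indicator stack built from explicit raw indicator matrices
make_stack <- function(dryness, greenness, heat, wetness,
                       index_year = 2001L) {
  nr <- nrow(dryness); nc <- ncol(dryness)
  valid <- !is.na(dryness) & !is.na(greenness) & !is.na(heat) & !is.na(wetness)
  structure(list(
    index_year = index_year, grid = tiny_grid(nr, nc),
    dryness = dryness, greenness = greenness, heat = heat, wetness = wetness,
    dryness_n = normalize_indicator(dryness, valid),
    greenness_n = normalize_indicator(greenness, valid),
    heat_n = normalize_indicator(heat, valid),
    wetness_n = normalize_indicator(wetness, valid),
    valid_mask = valid), class = "indicator_stack")
}

# uniform reflectance scene with one band overridden
flat_scene <- function(grid, date = "2000-10-01", fill = 0.1, ...) {
  over <- list(...)
  bands <- array(fill, dim = c(grid$n_rows, grid$n_cols, 7L),
                 dimnames = list(NULL, NULL, band_roles))
  for (role in names(over)) bands[, , role] <- over[[role]]
  reflectance_scene(grid, date, bands)
}

flat_thermal <- function(grid, date = "2000-10-01", nd = 15000) {
  thermal_scene(grid, date, matrix(nd, grid$n_rows, grid$n_cols))
}

## --- brute-force oracles ---------------------------------------------------

oracle_sen <- function(x, years = seq_along(x)) {
  ok <- !is.na(x); x <- x[ok]; years <- years[ok]
  slopes <- c()
  for (i in seq_along(x)) for (j in seq_along(x)) if (i < j)
    slopes <- c(slopes, (x[j] - x[i]) / (years[j] - years[i]))
  median(slopes)
}

oracle_mk <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  s <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    s <- s + sign(x[j] - x[i])
  tie_term <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    if (t > 1L) tie_term <- tie_term + t * (t - 1) * (2 * t + 5)
  }
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- if (s > 0 && var_s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0 && var_s > 0) (s + 1) / sqrt(var_s) else 0
  list(s = s, var_s = var_s, z = z)
}

# direct double-sum U, the non-recursive route
oracle_pettitt <- function(x, years = seq_along(x)) {
  ok <- !is.na(x); x <- x[ok]; years <- years[ok]
  n <- length(x)
  u <- numeric(n - 1L)
  for (t in seq_len(n - 1L)) {
    acc <- 0
    for (i in seq_len(t)) for (j in (t + 1L):n)
      acc <- acc + sign(x[j] - x[i])
    u[t] <- acc
  }
  k <- max(abs(u))
  tau_index <- which(abs(u) == k)[1L]
  list(u = u, k = k, tau_index = tau_index, tau_year = years[tau_index],
       p = min(1, 2 * exp(-6 * k^2 / (n^3 + n^2))))
}

# exhaustive nearest-center search with north-then-west tie preference
oracle_resample <- function(x, src_grid, dst_grid) {
  sc <- cell_centers(src_grid); dc <- cell_centers(dst_grid)
  out <- matrix(NA_real_, dst_grid$n_rows, dst_grid$n_cols)
  for (i in seq_len(dst_grid$n_rows)) for (j in seq_len(dst_grid$n_cols)) {
    d2 <- outer((sc$lat - dc$lat[i])^2, (sc$lon - dc$lon[j])^2, "+")
    best <- which(d2 <= min(d2) + 1e-18, arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    out[i, j] <- x[best[1L, 1L], best[1L, 2L]]  # grids assumed overlapping
  }
  out
}

# covariance by explicit summation, then eigen-decomposition
oracle_pc1_loadings <- function(x) {
  n <- nrow(x); p <- ncol(x)
  mu <- colSums(x) / n
  cv <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    acc <- 0
    for (r in seq_len(n)) acc <- acc + (x[r, a] - mu[a]) * (x[r, b] - mu[b])
    cv[a, b] <- acc / (n - 1)
  }
  eg <- eigen(cv, symmetric = TRUE)
  list(loadings = eg$vectors[, 1L],
       explained = eg$values / sum(eg$values))
}

# all series of the given lengths over the alphabet, as a list
enumerate_series <- function(lengths, alphabet = 0:2) {
  out <- list()
  for (n in lengths) {
    g <- as.matrix(expand.grid(rep(list(alphabet), n)))
    out <- c(out, lapply(seq_len(nrow(g)), function(i) unname(g[i, ])))
  }
  out
}
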
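# Synthetic MODIS-like scene generator: land-cover class maps with per-class
# spectral signatures, additive Gaussian noise, linear temporal drift, step
# changes at a known year and random cloud masking, so every downstream
# stage is testable without external data.

#' Land-cover classes of the synthetic generator
#' @export
synthetic_classes <- c("urban", "dense_vegetation", "agriculture",
                       "water", "bare_soil")

# per-class mean reflectance (band_roles order) and mean LST (deg C);
# water has NIR1 < red so NDVI < 0
.default_signatures <- function() {
  sig <- rbind(
    urban            = c(0.18, 0.22, 0.12, 0.15, 0.23, 0.28, 0.25),
    dense_vegetation = c(0.04, 0.45, 0.03, 0.07, 0.35, 0.15, 0.08),
    agriculture      = c(0.08, 0.35, 0.05, 0.10, 0.30, 0.20, 0.14),
    water            = c(0.05, 0.02, 0.06, 0.05, 0.01, 0.01, 0.01),
    bare_soil        = c(0.22, 0.28, 0.14, 0.18, 0.30, 0.35, 0.32))
  colnames(sig) <- band_roles
  list(reflectance = sig,
       lst_c = c(urban = 32, dense_vegetation = 26, agriculture = 29,
                 water = 24, bare_soil = 33))
}

.mmr_like_class_map <- function(n_rows, n_cols) {
  cls <- matrix("agriculture", n_rows, n_cols)
  fr <- row(cls) / n_rows; fc <- col(cls) / n_cols
  cls[fr <= 0.30] <- "dense_vegetation"          # vegetation in the north
  cls[fc <= 0.15 & fr > 0.30] <- "bare_soil"     # bare strip in the west
  cls[fc >= 0.70 & fr > 0.35] <- "urban"         # urban core in the east
  cls[fc >= 0.85 & fr > 0.85] <- "water"         # coastal water, south-east
  cls
}

#' Build a synthetic scenario
#'
#' A scenario fixes the grid, index years, land-cover class map, per-class
#' spectral/thermal signatures, noise level, per-class linear drift, an
#' optional step change at a known year, and the cloud-flag probability.
#' The class map is a deterministic function of the grid; the seed governs
#' only the random draws made when rendering.
#'
#' The `"mmr_like"` preset lays out an urban core in the east, dense
#' vegetation in the north, agriculture in the center, a bare-soil strip in
#' the west and coastal water in the south-east, with a vegetation-loss
#' step in the urban north-east at the 2018 index year.
#'
#' @param preset `"mmr_like"` or `"uniform"` (single-class agriculture).
#' @param n_rows,n_cols,cell_size_deg,origin_lon,origin_lat Grid spec.
#' @param years Integer index-year labels (default 2001:2025).
#' @param signatures List with `reflectance` (class x 7 matrix) and `lst_c`
#'   (named vector); defaults to built-in MODIS-like values.
#' @param noise_sd Additive Gaussian reflectance noise sd (default 0.02).
#' @param lst_noise_sd LST noise sd in deg C (default 0.8).
#' @param trend_spec Named list per class: `list(bands = <length-7 drift
#'   per year>, lst = <deg C per year>)`; classes omitted drift 0.
#' @param change_spec `NULL`, or `list(region = <logical matrix>,
#'   change_year = <year>, bands = <length-7 step>, lst = <deg C step>)`.
#' @param cloud_fraction Probability a scene cell is flagged unusable
#'   (default 0.15); must be in `[0, 1)`.
#' @param thermal_coarse_factor Integer >= 1; thermal scenes are rendered
#'   on a grid this many times coarser (default 2, mimicking the 1 km vs
#'   500 m product pairing); 1 disables.
#' @param seed Integer seed for the rendering draws.
#' @return A `synthetic_scenario` object.
#' @export
make_scenario <- function(preset = c("mmr_like", "uniform"),
                          n_rows = 30L, n_cols = 30L,
                          cell_size_deg = 0.005,
                          origin_lon = -36.1, origin_lat = -9.3,
                          years = 2001:2025,
                          signatures = .default_signatures(),
                          noise_sd = 0.02, lst_noise_sd = 0.8,
                          trend_spec = NULL, change_spec = NULL,
                          cloud_fraction = 0.15,
                          thermal_coarse_factor = 2L, seed = 1L) {
  preset <- match.arg(preset)
  if (cloud_fraction < 0 || cloud_fraction >= 1)
    stop("cloud_fraction must lie in [0, 1)")
  if (length(years) < 1L) stop("years must be non-empty")
  grid <- geo_grid(n_rows, n_cols, cell_size_deg, origin_lon, origin_lat)
  class_map <- switch(preset,
    mmr_like = .mmr_like_class_map(n_rows, n_cols),
    uniform = matrix("agriculture", n_rows, n_cols))
  if (!all(class_map %in% rownames(signatures$reflectance)))
    stop("class map contains classes without signatures")
  if (any(signatures$reflectance < .refl_valid_range[1L]) ||
      any(signatures$reflectance > .refl_valid_range[2L]))
    stop("signatures outside the valid reflectance range")

  if (is.null(trend_spec) && preset == "mmr_like") {
    # gentle greening of agriculture, slight urban drying
    trend_spec <- list(
      agriculture = list(bands = c(0, 0.002, 0, 0, 0.001, 0, 0), lst = 0),
      urban = list(bands = c(0.001, -0.001, 0, 0, 0, 0.001, 0.001),
                   lst = 0.02))
  }
  if (is.null(change_spec) && preset == "mmr_like" && 2018L %in% years) {
    region <- matrix(FALSE, n_rows, n_cols)
    region[row(region) / n_rows <= 0.55 & col(region) / n_cols >= 0.70 &
             class_map == "urban"] <- TRUE
    change_spec <- list(region = region, change_year = 2018L,
                        bands = c(0.02, -0.06, 0.01, 0, -0.04, 0.02, 0.02),
                        lst = 0.6)
  }
  if (!is.null(change_spec)) {
    check_raster_dims(change_spec$region, grid, "change region")
    if (!change_spec$change_year %in% years)
      stop("change_year must be one of the scenario years")
  }
  structure(list(
    grid = grid, years = as.integer(years), class_map = class_map,
    signatures = signatures, noise_sd = noise_sd,
    lst_noise_sd = lst_noise_sd, trend_spec = trend_spec,
    change_spec = change_spec, cloud_fraction = cloud_fraction,
    thermal_coarse_factor = as.integer(thermal_coarse_factor),
    seed = as.integer(seed), preset = preset),
    class = "synthetic_scenario")
}

# per-cell additive offset for band b (or lst) at elapsed dt years,
# including drift and, when past the change year inside the region, the step
.scenario_offset <- function(scn, what, band_idx, dt, year) {
  off <- matrix(0, scn$grid$n_rows, scn$grid$n_cols)
  for (cls in names(scn$trend_spec)) {
    spec <- scn$trend_spec[[cls]]
    rate <- if (what == "lst") spec$lst else spec$bands[band_idx]
    if (!is.null(rate) && rate != 0)
      off[scn$class_map == cls] <- rate * dt
  }
  cs <- scn$change_spec
  if (!is.null(cs) && year >= cs$change_year) {
    step <- if (what == "lst") cs$lst else cs$bands[band_idx]
    if (!is.null(step) && step != 0)
      off[cs$region] <- off[cs$region] + step
  }
  off
}

# coarsened grid covering the same extent (last partial cells truncated)
.coarse_grid <- function(grid, factor) {
  if (factor <= 1L) return(grid)
  geo_grid(max(1L, grid$n_rows %/% factor), max(1L, grid$n_cols %/% factor),
           grid$cell_size_deg * factor, grid$origin_lon, grid$origin_lat)
}

#' Render the dated scene series of a scenario
#'
#' For each index year Y, `scenes_per_season` acquisition dates are placed
#' evenly in the Sep (Y-1) - Mar (Y) window.  Per cell:
#' `value = signature + drift * (Y - first year) + step * [Y >= change
#' year, cell in region] + noise`, truncated to the valid reflectance
#' range.  Thermal scenes encode LST as `ND = round((LST_C + 273.15) /
#' 0.02)` on the (possibly coarser) thermal grid.  Quality words use the
#' single-bit convention (bit 0 set = cloud/shadow), drawn independently
#' per cell and date with probability `cloud_fraction`; the thermal scene
#' of a date shares the reflectance QA draw (resampled to its grid) to
#' mimic co-located cloudiness.  Deterministic given the scenario seed.
#'
#' @param scn A [make_scenario()] object.
#' @param scenes_per_season Scenes per index year (default 4).
#' @return List with `dates` (Date vector), `index_year` (label per date),
#'   `reflectance` (list of [reflectance_scene()]), `thermal` (list of
#'   [thermal_scene()]), `qa` (list of integer word matrices on the
#'   reflectance grid), `qa_thermal` (on the thermal grid), and
#'   `thermal_grid`.
#' @export
render_series <- function(scn, scenes_per_season = 4L) {
  stopifnot(inherits(scn, "synthetic_scenario"), scenes_per_season >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scn$seed)

  grid <- scn$grid
  tgrid <- .coarse_grid(grid, scn$thermal_coarse_factor)
  sig_r <- scn$signatures$reflectance[scn$class_map, , drop = FALSE]
  base_bands <- array(sig_r, dim = c(grid$n_rows, grid$n_cols, 7L))
  base_lst <- matrix(scn$signatures$lst_c[scn$class_map],
                     grid$n_rows, grid$n_cols)

  dates <- list(); iy <- integer(0)
  refl <- list(); therm <- list(); qa <- list(); qa_t <- list()
  k <- 0L
  for (y in scn$years) {
    win <- season_window(y)
    ds <- win[1L] + round(seq(0, as.numeric(win[2L] - win[1L]),
                              length.out = scenes_per_season))
    dt <- y - scn$years[1L]
    for (d in seq_along(ds)) {
      k <- k + 1L
      bands <- base_bands
      for (b in seq_len(7L)) {
        v <- base_bands[, , b] + .scenario_offset(scn, "band", b, dt, y)
        if (scn$noise_sd > 0)
          v <- v + matrix(stats::rnorm(length(v), sd = scn$noise_sd),
                          nrow(v), ncol(v))
        bands[, , b] <- pmin(pmax(v, .refl_valid_range[1L]),
                             .refl_valid_range[2L])
      }
      lst <- base_lst + .scenario_offset(scn, "lst", NA, dt, y)
      if (scn$lst_noise_sd > 0)
        lst <- lst + matrix(stats::rnorm(length(lst), sd = scn$lst_noise_sd),
                            nrow(lst), ncol(lst))
      lst_t <- resample_nearest(lst, grid, tgrid)
      nd <- pmax(round((lst_t + 273.15) / 0.02), 0)

      word <- matrix(stats::rbinom(grid$n_rows * grid$n_cols, 1L,
                                   scn$cloud_fraction),
                     grid$n_rows, grid$n_cols)
      word_t0 <- resample_nearest(word, grid, tgrid)
      word_t <- matrix(as.integer(word_t0), nrow(word_t0), ncol(word_t0))

      dates[[k]] <- ds[d]; iy[k] <- y
      refl[[k]] <- reflectance_scene(grid, ds[d], bands)
      therm[[k]] <- thermal_scene(tgrid, ds[d], nd)
      qa[[k]] <- word; qa_t[[k]] <- word_t
    }
  }
  list(dates = do.call(c, dates), index_year = iy, reflectance = refl,
       thermal = therm, qa = qa, qa_thermal = qa_t, thermal_grid = tgrid)
}

#' Ground-truth layers of a scenario
#'
#' Recovery scoring targets aligned to the scenario grid: the sign of the
#' injected greenness trend (from the NDVI time derivative at the class
#' signature: `sign(dNIR1 * red - dred * NIR1)`), the true change year
#' (nodata outside the affected region or when no change is specified),
#' and the affected-region mask.
#'
#' @param scn A [make_scenario()] object.
#' @return List with matrices `trend_sign` (-1/0/1), `change_year`
#'   (integer, `NA` = none), `region` (logical).
#' @export
truth_layers <- function(scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  grid <- scn$grid
  trend_sign <- matrix(0, grid$n_rows, grid$n_cols)
  for (cls in names(scn$trend_spec)) {
    spec <- scn$trend_spec[[cls]]
    a <- spec$bands[match("nir1", band_roles)]
    b <- spec$bands[match("red", band_roles)]
    sig <- scn$signatures$reflectance[cls, ]
    trend_sign[scn$class_map == cls] <-
      sign(a * sig[["red"]] - b * sig[["nir1"]])
  }
  change_year <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  region <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (!is.null(scn$change_spec)) {
    region <- scn$change_spec$region
    change_year[region] <- as.integer(scn$change_spec$change_year)
  }
  list(trend_sign = trend_sign, change_year = change_year, region = region)
}

#' Synthetic annual-index cube with known trend and step structure
#'
#' Generates a `rows x cols x years` cube of annual index values directly:
#' `value = base + drift * (year - first year) * [cell in drift region]
#' + step * [year >= change_year, cell in step region] + N(0, noise_sd)`.
#' This is the controlled test bed for per-pixel trend and change-point
#' recovery, where drift and step are expressed in index units (the scene
#' pipeline's per-year min-max renormalization makes band-level drift map
#' nonlinearly onto the final index, so recovery conditions are stated at
#' the index level).
#'
#' @param n_rows,n_cols Cube dimensions.
#' @param years Integer year labels (default 2001:2025).
#' @param base Baseline index value (default 0.5).
#' @param drift Annual drift in index units per year (default 0.01).
#' @param drift_region Logical matrix (default: western half drifts).
#' @param step Step size in index units (default 0, none).
#' @param step_region Logical matrix (default: same as `drift_region`).
#' @param change_year Year at/after which the step applies.
#' @param noise_sd Gaussian noise sd in index units (default 0.05).
#' @param seed Integer seed.
#' @return List: `cube`, `years`, `truth` (list with `drift_region`,
#'   `step_region`, `trend_sign`, `change_year`).
#' @export
make_index_cube <- function(n_rows = 20L, n_cols = 20L, years = 2001:2025,
                            base = 0.5, drift = 0.01, drift_region = NULL,
                            step = 0, step_region = NULL, change_year = NULL,
                            noise_sd = 0.05, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ny <- length(years)
  if (is.null(drift_region))
    drift_region <- col(matrix(0, n_rows, n_cols)) <= n_cols %/% 2L
  if (is.null(step_region)) step_region <- drift_region
  if (is.null(change_year)) change_year <- years[ceiling(ny * 0.7)]
  cube <- array(NA_real_, dim = c(n_rows, n_cols, ny))
  for (t in seq_len(ny)) {
    m <- matrix(base, n_rows, n_cols)
    m[drift_region] <- m[drift_region] + drift * (years[t] - years[1L])
    if (step != 0 && years[t] >= change_year)
      m[step_region] <- m[step_region] + step
    cube[, , t] <- m + matrix(stats::rnorm(n_rows * n_cols, sd = noise_sd),
                              n_rows, n_cols)
  }
  trend_sign <- matrix(0, n_rows, n_cols)
  trend_sign[drift_region] <- sign(drift)
  cy <- matrix(NA_integer_, n_rows, n_cols)
  if (step != 0) cy[step_region] <- as.integer(change_year)
  list(cube = cube, years = as.integer(years),
       truth = list(drift_region = drift_region, step_region = step_region,
                    trend_sign = trend_sign, change_year = cy))
}
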
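# Seasonal (Sep-Mar) annual compositing.
#
# Index-year convention: year Y labels the composite of September (Y-1)
# through March (Y), the austral spring-summer window; e.g. year 2001
# spans Sep 2000 - Mar 2001.

#' Season window of an index year
#'
#' @param index_year Integer label Y.
#' @param season_start,season_end `"MM-DD"` strings; defaults Sep 1 and
#'   Mar 31 (start belongs to year Y-1, end to year Y).
#' @return A length-2 `Date` vector (inclusive window).
#' @export
season_window <- function(index_year, season_start = "09-01",
                          season_end = "03-31") {
  c(as.Date(sprintf("%d-%s", index_year - 1L, season_start)),
    as.Date(sprintf("%d-%s", index_year, season_end)))
}

#' Composite dated scenes into an annual Sep-Mar layer stack
#'
#' Per cell and band, the composite is the chosen statistic over usable
#' (non-nodata) observations; a cell with zero usable observations in a
#' layer is nodata there.  The thermal composite is computed on the digital
#' numbers and then converted to Celsius (the conversion is affine, so it
#' commutes with the mean, and the median commutes with any monotone map).
#'
#' @param reflectance List of [reflectance_scene()]s dated within the
#'   window; typically already quality-masked.
#' @param thermal List of [thermal_scene()]s dated within the window, on
#'   the same grid.
#' @param index_year Integer label Y for the Sep (Y-1) - Mar (Y) window.
#' @param statistic `"median"` (default; robust to residual cloud) or
#'   `"mean"`.
#' @param season_start,season_end Window bounds, see [season_window()].
#' @return An `annual_composite`: list with `index_year`, `grid`, `bands`
#'   (rows x cols x 7), `lst_celsius` (matrix), `valid_mask` (matrix, TRUE
#'   where every layer received at least one usable observation).
#' @export
seasonal_composite <- function(reflectance, thermal, index_year,
                               statistic = c("median", "mean"),
                               season_start = "09-01", season_end = "03-31") {
  statistic <- match.arg(statistic)
  if (length(reflectance) == 0L || length(thermal) == 0L)
    stop("at least one reflectance and one thermal scene are required")
  win <- season_window(index_year, season_start, season_end)
  grid <- reflectance[[1L]]$grid
  for (s in c(reflectance, thermal)) {
    if (!grids_equal(s$grid, grid))
      stop("all scenes must share the common analysis grid")
    if (s$acq_date < win[1L] || s$acq_date > win[2L])
      stop(sprintf("scene dated %s falls outside the %s..%s window of index year %d",
                   format(s$acq_date), format(win[1L]), format(win[2L]),
                   index_year))
  }
  fun <- if (statistic == "median") function(v) stats::median(v, na.rm = TRUE)
         else function(v) mean(v, na.rm = TRUE)

  nr <- grid$n_rows; nc <- grid$n_cols
  bands <- array(NA_real_, dim = c(nr, nc, 7L),
                 dimnames = list(NULL, NULL, band_roles))
  for (b in seq_len(7L)) {
    stack <- vapply(reflectance, function(s) s$bands[, , b],
                    matrix(0, nr, nc))
    dim(stack) <- c(nr * nc, length(reflectance))
    v <- apply(stack, 1L, fun)
    v[is.nan(v)] <- NA
    bands[, , b] <- matrix(v, nr, nc)
  }
  dstack <- vapply(thermal, function(s) s$dn, matrix(0, nr, nc))
  dim(dstack) <- c(nr * nc, length(thermal))
  dn <- apply(dstack, 1L, fun)
  dn[is.nan(dn)] <- NA
  lst <- matrix(lst_celsius(dn), nr, nc)

  valid <- !is.na(lst)
  for (b in seq_len(7L)) valid <- valid & !is.na(bands[, , b])
  structure(list(index_year = as.integer(index_year), grid = grid,
                 bands = bands, lst_celsius = lst, valid_mask = valid),
            class = "annual_composite")
}
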
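#' Nearest-neighbor resampling to a target grid
#'
#' Each destination cell takes the value of the source cell whose center is
#' nearest the destination cell's center; no new values are created and
#' nodata propagates.  Equidistant ties resolve to the northern, then
#' western, candidate.  Destination cells whose centers fall outside the
#' source extent are nodata; an error is raised if none fall inside.
#'
#' @param x Matrix or 3-D array on `src_grid`.
#' @param src_grid,dst_grid [geo_grid()] objects in the same coordinate
#'   reference system.
#' @return `x` resampled onto `dst_grid` (same number of bands).
#' @export
resample_nearest <- function(x, src_grid, dst_grid) {
  stopifnot(inherits(src_grid, "geo_grid"), inherits(dst_grid, "geo_grid"))
  if (!identical(src_grid$crs_id, dst_grid$crs_id))
    stop("source and destination grids must share a CRS")
  was_matrix <- is.matrix(x)
  if (was_matrix) x <- array(x, dim = c(dim(x), 1L))
  check_raster_dims(x, src_grid, "x")

  ctr <- cell_centers(dst_grid)
  # index of the source cell whose center is nearest; ties go north/west,
  # i.e. to the smaller index, which ceiling() delivers at exact cell edges
  src_row <- ceiling((src_grid$origin_lat - ctr$lat) / src_grid$cell_size_deg)
  src_col <- ceiling((ctr$lon - src_grid$origin_lon) / src_grid$cell_size_deg)
  src_row[src_row < 1L | src_row > src_grid$n_rows] <- NA
  src_col[src_col < 1L | src_col > src_grid$n_cols] <- NA
  if (all(is.na(src_row)) || all(is.na(src_col)))
    stop("destination grid does not overlap the source grid")

  out <- array(NA_real_, dim = c(dst_grid$n_rows, dst_grid$n_cols, dim(x)[3L]))
  ok_r <- !is.na(src_row); ok_c <- !is.na(src_col)
  for (b in seq_len(dim(x)[3L]))
    out[ok_r, ok_c, b] <- x[src_row[ok_r], src_col[ok_c], b]
  if (was_matrix) out[, , 1L] else out
}

#' Resample a scene to a target grid
#'
#' Applies [resample_nearest()] to a scene's raster payload, returning a
#' scene of the same kind on `dst_grid`.
#'
#' @param scene [reflectance_scene()], [thermal_scene()] or [quality_mask()].
#' @param dst_grid Target [geo_grid()].
#' @return Scene of the same class on `dst_grid`.
#' @export
resample_scene <- function(scene, dst_grid) {
  if (inherits(scene, "reflectance_scene")) {
    reflectance_scene(dst_grid, scene$acq_date,
                      resample_nearest(scene$bands, scene$grid, dst_grid))
  } else if (inherits(scene, "thermal_scene")) {
    thermal_scene(dst_grid, scene$acq_date,
                  resample_nearest(scene$dn, scene$grid, dst_grid))
  } else if (inherits(scene, "quality_mask")) {
    u <- resample_nearest(scene$usable * 1, scene$grid, dst_grid)
    quality_mask(dst_grid, scene$acq_date, !is.na(u) & u > 0)
  } else stop("unknown scene class")
}
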
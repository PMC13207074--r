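#' Geographic analysis grid
#'
#' A regular geographic grid with square cells, edge-registered at the outer
#' corner of the top-left cell.  Rows run north to south, columns west to
#' east; cell coordinates are reported at cell centers.
#'
#' @param n_rows,n_cols Grid dimensions (rows x columns), both >= 1.
#' @param cell_size_deg Cell size in decimal degrees (square cells), > 0.
#' @param origin_lon,origin_lat Longitude/latitude in degrees of the outer
#'   (north-west) corner of the top-left cell.
#' @param crs_id Text identifier of the coordinate reference system;
#'   geographic WGS84 by default.
#'
#' @return An object of class `geo_grid`.
#' @examples
#' g <- geo_grid(10, 10, 0.005, origin_lon = -36.1, origin_lat = -9.3)
#' cell_centers(g)$lat[1:3]
#' @export
geo_grid <- function(n_rows, n_cols, cell_size_deg,
                     origin_lon, origin_lat, crs_id = "EPSG:4326") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be integers >= 1")
  if (!is.numeric(cell_size_deg) || length(cell_size_deg) != 1L ||
      !is.finite(cell_size_deg) || cell_size_deg <= 0)
    stop("cell_size_deg must be a single positive number")
  if (!is.finite(origin_lon) || !is.finite(origin_lat))
    stop("origin coordinates must be finite")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_size_deg = as.numeric(cell_size_deg),
         origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         crs_id = as.character(crs_id)),
    class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("<geo_grid> %d x %d cells of %g deg, NW corner (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cell_size_deg,
              x$origin_lon, x$origin_lat, x$crs_id))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [geo_grid()].
#' @return A list with `lon` (length `n_cols`, west to east) and `lat`
#'   (length `n_rows`, north to south) of cell centers in degrees.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "geo_grid"))
  list(
    lon = grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_deg,
    lat = grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size_deg)
}

#' Test two grids for equality
#'
#' @param a,b [geo_grid()] objects.
#' @param tol Coordinate tolerance in degrees.
#' @return `TRUE` when dimensions, cell size and origin agree within `tol`.
#' @export
grids_equal <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "geo_grid"), inherits(b, "geo_grid"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size_deg - b$cell_size_deg) <= tol &&
    abs(a$origin_lon - b$origin_lon) <= tol &&
    abs(a$origin_lat - b$origin_lat) <= tol
}

# internal: stop unless raster matrix dims match grid
check_raster_dims <- function(x, grid, what = "raster") {
  d <- dim(x)
  if (is.null(d) || d[1L] != grid$n_rows || d[2L] != grid$n_cols)
    stop(sprintf("%s dimensions (%s) do not match grid (%d x %d)",
                 what, paste(d, collapse = " x "), grid$n_rows, grid$n_cols))
  invisible(TRUE)
}
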
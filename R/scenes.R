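# Scene containers and GeoTIFF-backed scene I/O.
#
# Band order follows the MODIS surface-reflectance convention, bands 1-7:
# red, NIR1, blue, green, NIR2, SWIR1, SWIR2.

#' Reflectance band roles, in storage order
#'
#' MODIS-style band ordering: red, NIR1, blue, green, NIR2, SWIR1, SWIR2
#' (sensor bands 1-7).
#' @export
band_roles <- c("red", "nir1", "blue", "green", "nir2", "swir1", "swir2")

# nominal valid surface-reflectance range after scaling
.refl_valid_range <- c(-0.01, 1.6)

#' Construct a surface-reflectance scene
#'
#' @param grid [geo_grid()].
#' @param acq_date Acquisition date (`Date` or parseable string).
#' @param bands 3-D array `n_rows x n_cols x 7` of unit surface reflectance
#'   in band order [band_roles]; cells outside the nominal valid range
#'   `[-0.01, 1.6]` are set to `NA`.
#' @return An object of class `reflectance_scene`.
#' @export
reflectance_scene <- function(grid, acq_date, bands) {
  stopifnot(inherits(grid, "geo_grid"))
  if (length(dim(bands)) != 3L || dim(bands)[3L] != 7L)
    stop("bands must be an n_rows x n_cols x 7 array")
  check_raster_dims(bands, grid, "bands")
  bands[!is.na(bands) & (bands < .refl_valid_range[1L] |
                         bands > .refl_valid_range[2L])] <- NA
  dimnames(bands) <- list(NULL, NULL, band_roles)
  structure(list(grid = grid, acq_date = as.Date(acq_date), bands = bands),
            class = "reflectance_scene")
}

#' Construct a thermal scene of digital numbers
#'
#' Digital numbers (ND) decode to Kelvin as `0.02 * ND`; fill cells are `NA`.
#'
#' @param grid [geo_grid()].
#' @param acq_date Acquisition date.
#' @param dn Matrix of non-negative integer digital numbers; `NA` = fill.
#' @return An object of class `thermal_scene`.
#' @export
thermal_scene <- function(grid, acq_date, dn) {
  stopifnot(inherits(grid, "geo_grid"))
  check_raster_dims(dn, grid, "dn")
  if (any(dn < 0, na.rm = TRUE)) stop("digital numbers must be >= 0")
  structure(list(grid = grid, acq_date = as.Date(acq_date),
                 dn = matrix(as.numeric(dn), nrow(dn), ncol(dn))),
            class = "thermal_scene")
}

#' Construct a per-pixel usability mask
#'
#' @param grid [geo_grid()].
#' @param acq_date Acquisition date.
#' @param usable Logical matrix, `TRUE` = pixel retained.
#' @return An object of class `quality_mask`.
#' @export
quality_mask <- function(grid, acq_date, usable) {
  stopifnot(inherits(grid, "geo_grid"), is.logical(usable))
  check_raster_dims(usable, grid, "usable")
  structure(list(grid = grid, acq_date = as.Date(acq_date), usable = usable),
            class = "quality_mask")
}

#' Read a scene from a GeoTIFF
#'
#' Parses the grid from the file's geotransform.  Reflectance stored as
#' scaled integers (MOD09A1 convention, scale 1e-4) is converted to unit
#' reflectance when the file's metadata carries a scale factor or
#' `reflectance_scale` is given.
#'
#' @param path GeoTIFF path.
#' @param kind One of `"reflectance"`, `"thermal"`, `"quality"`.
#' @param reflectance_scale `NULL` to use the file's recorded scale (or none),
#'   or a numeric scale (e.g. `1e-4`) applied to the stored values.
#' @return A [reflectance_scene()], [thermal_scene()] or [quality_mask()].
#' @export
read_scene <- function(path, kind = c("reflectance", "thermal", "quality"),
                       reflectance_scale = NULL) {
  kind <- match.arg(kind)
  r <- read_geotiff(path)
  expected <- c(reflectance = 7L, thermal = 1L, quality = 1L)[[kind]]
  if (r$n_bands != expected)
    stop(sprintf("%s scene must have %d band(s), file has %d",
                 kind, expected, r$n_bands))
  desc <- if (is.list(r$description)) r$description else list()
  acq_date <- desc$acq_date
  if (is.null(acq_date)) acq_date <- .date_from_filename(path)
  if (kind == "reflectance") {
    scale <- reflectance_scale
    if (is.null(scale) && !is.null(desc$reflectance_scale))
      scale <- as.numeric(desc$reflectance_scale)
    vals <- r$values
    if (!is.null(scale) && scale != 1) vals <- vals * scale
    reflectance_scene(r$grid, acq_date, vals)
  } else if (kind == "thermal") {
    thermal_scene(r$grid, acq_date, r$values[, , 1L])
  } else {
    quality_mask(r$grid, acq_date, r$values[, , 1L] > 0 & !is.na(r$values[, , 1L]))
  }
}

.date_from_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexpr("\\d{4}-\\d{2}-\\d{2}", basename(path)))
  if (length(m) == 0L)
    stop("no acquisition date in file metadata or filename: ", path)
  m
}

#' Write a scene to a GeoTIFF
#'
#' @param scene A [reflectance_scene()], [thermal_scene()] or
#'   [quality_mask()]; quality masks are written as uint8 (1 = usable).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  if (inherits(scene, "reflectance_scene")) {
    write_geotiff(scene$bands, scene$grid, path, "float32",
                  description = list(acq_date = format(scene$acq_date),
                                     kind = "reflectance"))
  } else if (inherits(scene, "thermal_scene")) {
    write_geotiff(scene$dn, scene$grid, path, "int32", nodata = -1,
                  description = list(acq_date = format(scene$acq_date),
                                     kind = "thermal"))
  } else if (inherits(scene, "quality_mask")) {
    write_geotiff(scene$usable * 1L, scene$grid, path, "uint8", nodata = 255,
                  description = list(acq_date = format(scene$acq_date),
                                     kind = "quality"))
  } else stop("unknown scene class")
  invisible(path)
}

#' Quality bit specifications
#'
#' A bit specification is a list of tests, each `list(bits = c(low, high),
#' ok = <accepted values>)`, applied to the per-pixel integer quality word.
#' A pixel is retained only if every extracted bit field takes an accepted
#' value.  `qa_bits_mod09a1()` mirrors the MOD09A1 state flags (cloud state
#' bits 0-1 must be clear, cloud shadow bit 2 must be 0);
#' `qa_bits_single()` is the single-bit convention used by the synthetic
#' generator (bit 0 set = unusable).
#'
#' @return A bit specification list.
#' @export
qa_bits_mod09a1 <- function() {
  list(cloud_state = list(bits = c(0L, 1L), ok = 0L),
       cloud_shadow = list(bits = c(2L, 2L), ok = 0L))
}

#' @rdname qa_bits_mod09a1
#' @export
qa_bits_single <- function() {
  list(unusable = list(bits = c(0L, 0L), ok = 0L))
}

# extract bit field [low, high] from integer words
.extract_bits <- function(word, low, high) {
  bitwAnd(bitwShiftR(as.integer(word), low), bitwShiftL(1L, high - low + 1L) - 1L)
}

#' Mask a scene with a quality word raster
#'
#' Cells whose quality word fails any bit test of `bit_spec`, or whose word
#' is `NA`, become nodata; retained cells are passed through bit-exactly.
#'
#' @param scene A [reflectance_scene()] or [thermal_scene()].
#' @param qa Integer matrix of quality words, co-registered with `scene`.
#' @param bit_spec Bit specification, see [qa_bits_mod09a1()].
#' @return The scene with failing cells set to `NA`.
#' @export
apply_quality_mask <- function(scene, qa, bit_spec = qa_bits_mod09a1()) {
  grid <- scene$grid
  check_raster_dims(qa, grid, "qa")
  keep <- !is.na(qa)
  for (test in bit_spec) {
    fld <- .extract_bits(ifelse(is.na(qa), 0L, qa),
                         test$bits[1L], test$bits[2L])
    keep <- keep & (fld %in% test$ok)
  }
  dim(keep) <- dim(qa)
  if (inherits(scene, "reflectance_scene")) {
    for (b in seq_len(dim(scene$bands)[3L]))
      scene$bands[, , b][!keep] <- NA
  } else if (inherits(scene, "thermal_scene")) {
    scene$dn[!keep] <- NA
  } else stop("scene must be a reflectance_scene or thermal_scene")
  scene
}
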
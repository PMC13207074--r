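# The four RSEI indicator rasters: NDBSI dryness, NDVI greenness, LST heat
# and tasseled-cap wetness, computed from a Sep-Mar annual composite.

# tasseled-cap wetness coefficients for the 7 reflectance bands
.wetness_coef <- c(red = 0.1147, nir1 = 0.2489, blue = 0.2408,
                   green = 0.3132, nir2 = 0.3122, swir1 = -0.6416,
                   swir2 = -0.5087)

.safe_ratio <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA
  out
}

#' NDVI greenness
#'
#' Normalized difference vegetation index, `(NIR1 - red)/(NIR1 + red)`,
#' ranging from -1 (water) to 1 (dense vegetation).  Zero denominators
#' yield nodata.
#'
#' @param composite An `annual_composite` from [seasonal_composite()], or a
#'   list with a `bands` array in [band_roles] order.
#' @return Greenness matrix in `[-1, 1]`.
#' @export
ndvi <- function(composite) {
  b <- composite$bands
  .safe_ratio(b[, , "nir1"] - b[, , "red"], b[, , "nir1"] + b[, , "red"])
}

#' NDBSI dryness (IBI, SI and their mean)
#'
#' Index-based built-up index
#' `IBI = (A - B)/(A + B)` with `A = 2*SWIR1/(SWIR1 + NIR1)` and
#' `B = NIR1/(NIR1 + red) + green/(green + SWIR1)`; bare-soil index
#' `SI = ((SWIR1 + red) - (NIR1 + blue)) / ((SWIR1 + red) + (NIR1 + blue))`;
#' dryness is `(IBI + SI)/2`, ranging from -1 (vegetated) to 1 (impervious).
#' Any zero sub-denominator yields nodata (composites over water or fill can
#' produce zeros).
#'
#' @inheritParams ndvi
#' @return List with matrices `ibi`, `si`, `dryness`.
#' @export
ndbsi <- function(composite) {
  b <- composite$bands
  swir1 <- b[, , "swir1"]; nir1 <- b[, , "nir1"]; red <- b[, , "red"]
  green <- b[, , "green"]; blue <- b[, , "blue"]
  a <- .safe_ratio(2 * swir1, swir1 + nir1)
  bb <- .safe_ratio(nir1, nir1 + red) + .safe_ratio(green, green + swir1)
  ibi <- .safe_ratio(a - bb, a + bb)
  si <- .safe_ratio((swir1 + red) - (nir1 + blue),
                    (swir1 + red) + (nir1 + blue))
  list(ibi = ibi, si = si, dryness = (ibi + si) / 2)
}

#' Tasseled-cap wetness
#'
#' Fixed linear combination of the 7 reflectance bands
#' (`0.1147 red + 0.2489 NIR1 + 0.2408 blue + 0.3132 green + 0.3122 NIR2
#' - 0.6416 SWIR1 - 0.5087 SWIR2`) indexing surface moisture.
#'
#' @inheritParams ndvi
#' @return Wetness matrix (dimensionless).
#' @export
tc_wetness <- function(composite) {
  b <- composite$bands
  out <- 0
  for (role in band_roles) out <- out + .wetness_coef[[role]] * b[, , role]
  out
}

#' Decode thermal digital numbers to land surface temperature
#'
#' `LST[K] = 0.02 * ND`, reported in Celsius: `0.02 * ND - 273.15`.
#' Fill (`NA`) digital numbers stay nodata.
#'
#' @param nd Numeric vector or matrix of digital numbers.
#' @return LST in degrees Celsius, same shape as `nd`.
#' @export
lst_celsius <- function(nd) {
  0.02 * nd - 273.15
}

#' Compute the four-indicator stack for one index year
#'
#' Derives dryness, greenness, heat and wetness from an annual composite
#' and min-max normalizes each over the cells where all four are defined.
#'
#' @param composite An `annual_composite` from [seasonal_composite()].
#' @return An `indicator_stack`: list with `index_year`, `grid`, raw
#'   matrices `dryness`, `greenness`, `heat`, `wetness`, normalized
#'   counterparts `*_n` in `[0, 1]`, and the shared `valid_mask`.
#' @export
indicator_stack <- function(composite) {
  stopifnot(inherits(composite, "annual_composite"))
  greenness <- ndvi(composite)
  dryness <- ndbsi(composite)$dryness
  heat <- composite$lst_celsius
  wetness <- tc_wetness(composite)
  valid <- composite$valid_mask & !is.na(dryness) & !is.na(greenness) &
    !is.na(heat) & !is.na(wetness)
  for (nm in c("dryness", "greenness", "heat", "wetness")) {
    x <- get(nm); x[!valid] <- NA; assign(nm, x)
  }
  structure(list(
    index_year = composite$index_year, grid = composite$grid,
    dryness = dryness, greenness = greenness, heat = heat, wetness = wetness,
    dryness_n = normalize_indicator(dryness, valid),
    greenness_n = normalize_indicator(greenness, valid),
    heat_n = normalize_indicator(heat, valid),
    wetness_n = normalize_indicator(wetness, valid),
    valid_mask = valid), class = "indicator_stack")
}
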
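# RSEI construction: min-max normalization, per-year PCA, orientation,
# five-class ecological quality scheme and annual descriptive statistics.

#' Ecological quality class labels
#'
#' Poor `[0, 0.2)`, Fair `[0.2, 0.4)`, Moderate `[0.4, 0.6)`,
#' Good `[0.6, 0.8)`, Excellent `[0.8, 1]`.  Boundaries belong to the upper
#' class; the top interval is closed.
#' @export
rsei_class_labels <- c("Poor", "Fair", "Moderate", "Good", "Excellent")

#' Min-max normalize an indicator raster
#'
#' `(I - Imin) / (Imax - Imin)` with the minimum and maximum taken over the
#' valid cells of that year's raster, so the output lies in `[0, 1]` and
#' attains both endpoints.
#'
#' @param x Numeric matrix (or vector).
#' @param valid_mask Optional logical mask of cells to use; `NA` cells are
#'   always excluded.
#' @return Normalized raster; masked/nodata cells are `NA`.
#' @export
normalize_indicator <- function(x, valid_mask = NULL) {
  v <- !is.na(x)
  if (!is.null(valid_mask)) v <- v & valid_mask
  if (sum(v) < 2L) stop("need at least 2 valid cells to normalize")
  rng <- range(x[v])
  if (rng[1L] == rng[2L])
    stop("degenerate input: indicator is constant over valid cells")
  out <- (x - rng[1L]) / (rng[2L] - rng[1L])
  out[!v] <- NA
  out
}

#' First principal component of the four normalized indicators
#'
#' Eigen-decomposition of the 4x4 covariance matrix of the normalized
#' indicators over valid cells (cells are observations).  The PC1 sign is
#' made deterministic by forcing the largest-magnitude loading positive.
#'
#' @param x Numeric matrix with one column per indicator (dryness,
#'   greenness, heat, wetness order), one row per valid cell.
#' @return List with `loadings` (unit-norm, named), `explained_fraction`
#'   (sums to 1) and `scores` (centered PC1 scores, one per row).
#' @keywords internal
.pc1 <- function(x) {
  cv <- stats::cov(x)
  if (sum(diag(cv)) <= 0) stop("zero total variance across indicators")
  eg <- eigen(cv, symmetric = TRUE)
  w <- eg$vectors[, 1L]
  if (w[which.max(abs(w))] < 0) w <- -w
  names(w) <- colnames(x)
  list(loadings = w,
       explained_fraction = eg$values / sum(eg$values),
       scores = as.vector(scale(x, center = TRUE, scale = FALSE) %*% w))
}

#' Compute the RSEI layer for one index year
#'
#' Runs PCA on the four normalized indicators over valid cells and takes
#' PC1.  Orientation: when the PC1 loadings of greenness and wetness (the
#' ecology-positive indicators) are negative, the component points away
#' from ecological quality and `RSEI0 = 1 - PC1`; otherwise `RSEI0 = PC1`.
#' If the two loadings disagree in sign the greenness loading decides and a
#' warning is issued.  `RSEIn` is the min-max rescaling of `RSEI0` over the
#' year's valid cells, so it spans `[0, 1]`.
#'
#' @param stack An [indicator_stack()].
#' @param min_valid Minimum number of valid cells (default 5).
#' @return An `rsei_layer`: list with `index_year`, `grid`, `rsei0`,
#'   `rsein`, `class_raster` (integer 1-5 coded per [rsei_class_labels]),
#'   `pca` (list: `loadings`, `explained_fraction`), `valid_mask`.
#' @export
compute_rsei <- function(stack, min_valid = 5L) {
  stopifnot(inherits(stack, "indicator_stack"))
  v <- stack$valid_mask
  if (sum(v) < min_valid)
    stop("fewer than ", min_valid, " valid cells")
  x <- cbind(dryness = stack$dryness_n[v], greenness = stack$greenness_n[v],
             heat = stack$heat_n[v], wetness = stack$wetness_n[v])
  pca <- .pc1(x)
  g_load <- pca$loadings[["greenness"]]
  w_load <- pca$loadings[["wetness"]]
  if (sign(g_load) != sign(w_load) && g_load != 0 && w_load != 0)
    warning("greenness and wetness PC1 loadings disagree in sign; ",
            "orientation decided by the greenness loading")
  flip <- g_load < 0
  scores <- if (flip) 1 - pca$scores else pca$scores

  rsei0 <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  rsei0[v] <- scores
  rsein <- rsei0
  rsein[v] <- normalize_indicator(scores)
  structure(list(
    index_year = stack$index_year, grid = stack$grid,
    rsei0 = rsei0, rsein = rsein,
    class_raster = classify_rsei(rsein),
    pca = list(loadings = pca$loadings,
               explained_fraction = pca$explained_fraction,
               flipped = flip),
    valid_mask = v), class = "rsei_layer")
}

#' Classify a normalized RSEI raster into five quality classes
#'
#' `[0, 0.2)` Poor, `[0.2, 0.4)` Fair, `[0.4, 0.6)` Moderate, `[0.6, 0.8)`
#' Good, `[0.8, 1]` Excellent; nodata preserved.  Values outside `[0, 1]`
#' are an error.
#'
#' @param rsein Matrix (or vector) of normalized RSEI values.
#' @return Integer raster, 1 (Poor) .. 5 (Excellent), `NA` preserved, with
#'   a `labels` attribute.
#' @export
classify_rsei <- function(rsein) {
  vals <- rsein[!is.na(rsein)]
  if (any(vals < 0 | vals > 1))
    stop("RSEIn values must lie in [0, 1]")
  cls <- findInterval(rsein, c(0.2, 0.4, 0.6, 0.8)) + 1L
  cls[is.na(rsein)] <- NA_integer_
  if (!is.null(dim(rsein))) dim(cls) <- dim(rsein)
  attr(cls, "labels") <- rsei_class_labels
  cls
}

#' Annual descriptive statistics of a normalized RSEI raster
#'
#' Order statistics use linear-interpolation quantiles, the standard
#' deviation uses the `n - 1` denominator, and the coefficient of variation
#' is `100 * sd / mean` (percent).
#'
#' @param rsein Matrix of normalized RSEI values (`NA` = nodata).
#' @param year Index-year label.
#' @return One-row `data.frame`: `year, min, q1, mean, median, q3, max,
#'   sd, cv`.
#' @export
annual_stats <- function(rsein, year) {
  v <- rsein[!is.na(rsein)]
  if (length(v) < 2L) stop("need at least 2 valid cells")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m <- mean(v); s <- stats::sd(v)
  data.frame(year = as.integer(year), min = min(v), q1 = q[1L], mean = m,
             median = q[2L], q3 = q[3L], max = max(v), sd = s,
             cv = if (m != 0) 100 * s / m else NA_real_)
}
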
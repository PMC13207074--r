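# Per-pixel Theil-Sen slope and Mann-Kendall trend significance over the
# annual RSEI series.

#' Trend significance class codes
#'
#' Integer codes -3..3: negative = decreasing, positive = increasing,
#' magnitude 1/2/3 = significant at the 90/95/99% confidence level,
#' 0 = no significant trend.
#' @export
trend_class_labels <- c(`-3` = "dec99", `-2` = "dec95", `-1` = "dec90",
                        `0` = "none", `1` = "inc90", `2` = "inc95",
                        `3` = "inc99")

#' Theil-Sen slope of an annual series
#'
#' The median of all pairwise slopes `(x[j] - x[i]) / (years[j] - years[i])`
#' over `i < j`; robust to outliers.  Missing values are skipped.
#'
#' @param values Numeric series (may contain `NA`).
#' @param years Integer year labels, strictly increasing, same length.
#' @param statistic `"median"` (the Theil-Sen definition, default) or
#'   `"mean"` of the pairwise slopes.
#' @return The slope, in index units per year.
#' @export
sen_slope <- function(values, years = seq_along(values),
                      statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(length(values) == length(years))
  ok <- !is.na(values)
  x <- values[ok]; t <- years[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 non-missing values")
  ij <- utils::combn(n, 2L)
  slopes <- (x[ij[2L, ]] - x[ij[1L, ]]) / (t[ij[2L, ]] - t[ij[1L, ]])
  if (statistic == "median") stats::median(slopes) else mean(slopes)
}

#' Mann-Kendall trend test
#'
#' `S` is the count of concordant minus discordant time-ordered pairs;
#' `Var(S) = [n(n-1)(2n+5) - sum_ties t(t-1)(2t+5)] / 18` (tie-corrected);
#' `Z` is the continuity-corrected normal deviate (`(S-1)/sqrt(Var)` for
#' `S > 0`, 0 for `S = 0`, `(S+1)/sqrt(Var)` for `S < 0`).  The
#' significance class compares `|Z|` against the 90/95/99% critical values
#' with the sign of `Z` giving the direction.
#'
#' @param values Numeric series (may contain `NA`; skipped).
#' @param min_n Minimum number of non-missing values (default 4); below it
#'   the result is all-`NA` with class `none`.
#' @param z_crit Critical values for the 90/95/99% levels (two-tailed);
#'   defaults `c(1.645, 1.96, 2.574)`.
#' @return List: `s`, `var_s`, `z`, `sig_code` (-3..3), `sig_class`
#'   (label), `n`.
#' @export
mann_kendall <- function(values, min_n = 4L,
                         z_crit = c(1.645, 1.96, 2.574)) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < min_n)
    return(list(s = NA_integer_, var_s = NA_real_, z = NA_real_,
                sig_code = NA_integer_, sig_class = NA_character_, n = n))
  d <- sign(outer(x, x, function(a, b) b - a))  # d[i, j] = sign(x[j] - x[i])
  s <- sum(d[upper.tri(d)])                     # over time-ordered pairs i < j

  ties <- table(x)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0 && var_s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0 && var_s > 0) (s + 1) / sqrt(var_s)
       else 0
  level <- if (abs(z) > z_crit[3L]) 3L
           else if (abs(z) > z_crit[2L]) 2L
           else if (abs(z) > z_crit[1L]) 1L
           else 0L
  code <- level * sign(z)
  list(s = as.integer(s), var_s = var_s, z = z, sig_code = as.integer(code),
       sig_class = unname(trend_class_labels[as.character(code)]), n = n)
}

#' Per-pixel trend map over an annual raster cube
#'
#' Applies [sen_slope()] and [mann_kendall()] independently at each cell of
#' a `rows x cols x years` cube; missing years at a cell are skipped, not
#' imputed, and cells with fewer than `min_years` valid years are nodata.
#'
#' @param cube 3-D array `n_rows x n_cols x n_years` of annual values.
#' @param years Integer year labels, one per cube slice.
#' @param min_years Minimum valid years per cell (default 10).
#' @param z_crit See [mann_kendall()].
#' @param slope_statistic See [sen_slope()].
#' @return A `trend_layer`: list with matrices `beta`, `s`, `var_s`, `z`,
#'   `sig_code` (-3..3, `NA` = nodata), plus `years`.
#' @export
trend_map <- function(cube, years, min_years = 10L,
                      z_crit = c(1.645, 1.96, 2.574),
                      slope_statistic = "median") {
  stopifnot(length(dim(cube)) == 3L, dim(cube)[3L] == length(years))
  nr <- dim(cube)[1L]; nc <- dim(cube)[2L]
  beta <- s <- var_s <- z <- code <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- cube[i, j, ]
    if (sum(!is.na(v)) < max(min_years, 2L)) next
    beta[i, j] <- sen_slope(v, years, statistic = slope_statistic)
    mk <- mann_kendall(v, min_n = min_years, z_crit = z_crit)
    s[i, j] <- mk$s; var_s[i, j] <- mk$var_s; z[i, j] <- mk$z
    code[i, j] <- mk$sig_code
  }
  structure(list(beta = beta, s = s, var_s = var_s, z = z,
                 sig_code = code, years = years), class = "trend_layer")
}

#' Tabulate trend-class areas
#'
#' @param trend A `trend_layer` from [trend_map()].
#' @return `data.frame` with `class`, `cells`, `percent` (of analyzable
#'   cells) for every class in [trend_class_labels], zeros included.
#' @export
trend_class_areas <- function(trend) {
  codes <- trend$sig_code[!is.na(trend$sig_code)]
  counts <- vapply(as.integer(names(trend_class_labels)),
                   function(k) sum(codes == k), 0L)
  data.frame(class = unname(trend_class_labels), cells = counts,
             percent = if (length(codes)) 100 * counts / length(codes)
                       else rep(0, length(counts)))
}
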
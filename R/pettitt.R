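# Per-pixel Pettitt single change-point detection on the annual RSEI series.

#' Pettitt change-point test
#'
#' Rank-based single change-point test.  For a series `x[1..T]`,
#' `U[t] = sum over i <= t, j > t of sign(x[j] - x[i])`, computed by the
#' recursive update and identical to the direct double sum;
#' `K = max |U[t]|` with the most probable change point `tau` at the argmax
#' (earliest year on ties), reported as the last year of the first segment.
#' The approximate significance is `p = min(1, 2 exp(-6 K^2 / (T^3 + T^2)))`.
#' Missing values are dropped and the series compressed to its `n` valid
#' observations (the rank statistic ignores unequal spacing).
#'
#' @param values Numeric series (may contain `NA`).
#' @param years Integer year labels, same length as `values`.
#' @param min_n Minimum number of non-missing values (default 4).
#' @return List: `u` (length `n - 1`), `k_stat`, `tau_index`, `tau_year`,
#'   `p_approx`, `n`.
#' @export
pettitt <- function(values, years = seq_along(values), min_n = 4L) {
  stopifnot(length(values) == length(years))
  ok <- !is.na(values)
  x <- values[ok]; yr <- years[ok]
  n <- length(x)
  if (n < min_n)
    return(list(u = NULL, k_stat = NA_real_, tau_index = NA_integer_,
                tau_year = NA_integer_, p_approx = NA_real_, n = n))
  # U[t] via the recursion U[t] = U[t-1] + sum_j sign(x[j] - x[t]);
  # row t of the full sign matrix supplies the update term
  d <- sign(outer(x, x, function(a, b) b - a))  # d[t, j] = sign(x[j] - x[t])
  v <- rowSums(d)
  u <- cumsum(v)[seq_len(n - 1L)]
  k <- max(abs(u))
  tau_index <- which.max(abs(u))  # earliest on ties
  p <- min(1, 2 * exp(-6 * k^2 / (n^3 + n^2)))
  list(u = u, k_stat = k, tau_index = as.integer(tau_index),
       tau_year = as.integer(yr[tau_index]), p_approx = p, n = n)
}

#' Per-pixel Pettitt change-point map over an annual raster cube
#'
#' Applies [pettitt()] at each cell; cells with fewer than `min_years`
#' valid years are nodata.  `tau_year_sig` masks the change year to cells
#' significant at `alpha`.
#'
#' @param cube 3-D array `n_rows x n_cols x n_years`.
#' @param years Integer year labels, one per slice.
#' @param min_years Minimum valid years per cell (default 10).
#' @param alpha Significance level for the mask (default 0.10).
#' @return A `changepoint_layer`: list with matrices `k_stat`, `tau_year`,
#'   `p_approx`, `significant` (logical), `tau_year_sig`, plus `years`,
#'   `alpha`.
#' @export
changepoint_map <- function(cube, years, min_years = 10L, alpha = 0.10) {
  stopifnot(length(dim(cube)) == 3L, dim(cube)[3L] == length(years))
  nr <- dim(cube)[1L]; nc <- dim(cube)[2L]
  k <- p <- matrix(NA_real_, nr, nc)
  tau <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- cube[i, j, ]
    if (sum(!is.na(v)) < min_years) next
    pt <- pettitt(v, years, min_n = min_years)
    k[i, j] <- pt$k_stat; tau[i, j] <- pt$tau_year; p[i, j] <- pt$p_approx
  }
  sig <- !is.na(p) & p < alpha
  tau_sig <- tau
  tau_sig[!sig] <- NA_integer_
  structure(list(k_stat = k, tau_year = tau, p_approx = p,
                 significant = sig, tau_year_sig = tau_sig,
                 years = years, alpha = alpha),
            class = "changepoint_layer")
}

#' Histogram of significant change years
#'
#' @param cp A `changepoint_layer` from [changepoint_map()].
#' @return `data.frame` with `year` and `cells` counting cells whose
#'   significant change point falls in that year (all series years listed,
#'   zeros included).
#' @export
changepoint_histogram <- function(cp) {
  yrs <- cp$years
  counts <- vapply(yrs, function(y)
    sum(cp$tau_year_sig == y, na.rm = TRUE), 0L)
  data.frame(year = as.integer(yrs), cells = counts)
}
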
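#' Paired measurements of two methods
#'
#' @param x,y equal-length numeric vectors: the same samples measured by
#'   method A (`x`) and method B (`y`).
#' @param labels character vector of length 2 naming the methods.
#' @return list of class `paired_measurements` with `x`, `y`, `n`, `labels`.
#' @export
paired_measurements <- function(x, y, labels = c("A", "B")) {
  if (length(x) != length(y)) stop("paired_measurements: x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("paired_measurements: values must be finite")
  structure(list(x = as.numeric(x), y = as.numeric(y), n = length(x),
                 labels = as.character(labels)),
            class = "paired_measurements")
}

#' Pearson correlation of paired measurements
#'
#' @param pairs a [paired_measurements()] (n >= 3, both vectors with nonzero
#'   variance).
#' @return list `r`, `r_squared`, `n`.
#' @export
pearson_correlation <- function(pairs) {
  if (pairs$n < 3) stop("pearson_correlation: need n >= 3")
  if (sd(pairs$x) == 0 || sd(pairs$y) == 0)
    stop("pearson_correlation: zero variance - correlation undefined")
  r <- cor(pairs$x, pairs$y)
  list(r = r, r_squared = r^2, n = pairs$n)
}

#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression. All pairwise slopes
#' `S_ij = (y_j - y_i) / (x_j - x_i)` for `i < j` with `x_i != x_j` are
#' formed; slopes exactly equal to -1 are excluded. With `K` the number of
#' slopes below -1, the slope estimate is the median of the sorted slopes
#' shifted by offset `K` (so the estimator is symmetric in x and y). The
#' intercept is `median(y - slope * x)`. Confidence limits come from the
#' normal-approximation rank bounds with variance `n (n-1) (2n+5) / 18`; the
#' intercept limits are recomputed from the slope limit endpoints.
#'
#' @param pairs a [paired_measurements()] (n >= 3, not all points identical).
#' @param conf_level confidence level for the rank-based limits.
#' @return object of class `passing_bablok_result`: `slope`, `slope_ci`,
#'   `intercept`, `intercept_ci`, `n`, `n_slopes`.
#' @export
passing_bablok <- function(pairs, conf_level = 0.95) {
  x <- pairs$x; y <- pairs$y; n <- pairs$n
  if (n < 3) stop("passing_bablok: need n >= 3")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- x[ij[, 2]] - x[ij[, 1]]
  dy <- y[ij[, 2]] - y[ij[, 1]]
  ok <- dx != 0
  s <- dy[ok] / dx[ok]
  s <- s[s != -1]
  if (length(s) == 0) stop("passing_bablok: slope undefined (all x identical)")
  s <- sort(s)
  N <- length(s)
  K <- sum(s < -1)
  at <- function(idx) s[min(max(idx, 1L), N)]
  slope <- if (N %% 2 == 1) at((N + 1) %/% 2 + K)
           else (at(N %/% 2 + K) + at(N %/% 2 + 1 + K)) / 2
  z <- qnorm(1 - (1 - conf_level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  slope_lo <- at(M1 + K)
  slope_hi <- at(M2 + K)
  intercept <- median(y - slope * x)
  int_lo <- median(y - slope_hi * x)
  int_hi <- median(y - slope_lo * x)
  structure(list(slope = slope, slope_ci = c(slope_lo, slope_hi),
                 intercept = intercept, intercept_ci = c(int_lo, int_hi),
                 n = n, n_slopes = N, conf_level = conf_level),
            class = "passing_bablok_result")
}

#' @export
print.passing_bablok_result <- function(x, ...) {
  cat(sprintf("<passing_bablok_result> slope %.4f (%.4f~%.4f), intercept %.4f (%.4f~%.4f), n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2], x$n))
  invisible(x)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences `d_i = y_i - x_i`; mean bias with its confidence interval
#' (t-based by default, z optional) and limits of agreement
#' `bias +/- 1.96 * SD(d)`.
#'
#' @param pairs a [paired_measurements()] (n >= 2).
#' @param conf_level confidence level for the bias CI.
#' @param ci_method `"t"` (default) or `"z"` for the bias CI multiplier.
#' @return object of class `bland_altman_result`: `mean_bias`, `bias_ci`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(pairs, conf_level = 0.95, ci_method = c("t", "z")) {
  ci_method <- match.arg(ci_method)
  if (pairs$n < 2) stop("bland_altman: need n >= 2")
  d <- pairs$y - pairs$x
  bias <- mean(d); s <- sd(d); n <- pairs$n
  mult <- if (ci_method == "t") qt(1 - (1 - conf_level) / 2, df = n - 1)
          else qnorm(1 - (1 - conf_level) / 2)
  half <- mult * s / sqrt(n)
  structure(list(mean_bias = bias, bias_ci = c(bias - half, bias + half),
                 sd_diff = s, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = n, ci_method = ci_method),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman_result> bias %.4f (%.4f~%.4f), LoA %.4f~%.4f, n = %d\n",
              x$mean_bias, x$bias_ci[1], x$bias_ci[2], x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Restrict paired measurements to a concentration subrange
#'
#' Retains the pairs whose reference value (method A, method B, or the pair
#' mean) lies in `[lo, hi]`, for re-running the comparison statistics on a
#' clinically relevant range.
#'
#' @param pairs a [paired_measurements()].
#' @param lo,hi closed range bounds.
#' @param reference which value defines membership: `"A"` (default, the
#'   comparator method), `"B"`, or `"mean"`.
#' @return a filtered [paired_measurements()].
#' @export
subrange <- function(pairs, lo, hi, reference = c("A", "B", "mean")) {
  reference <- match.arg(reference)
  if (lo > hi) stop("subrange: lo must be <= hi")
  ref <- switch(reference, A = pairs$x, B = pairs$y, mean = (pairs$x + pairs$y) / 2)
  keep <- ref >= lo & ref <= hi
  if (!any(keep))
    stop("subrange: no pairs with ", reference, " value in [", lo, ", ", hi, "]")
  paired_measurements(pairs$x[keep], pairs$y[keep], pairs$labels)
}
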
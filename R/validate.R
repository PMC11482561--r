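#' A replicate measurement series at one concentration level
#'
#' @param level_label label for the level.
#' @param expected expected (nominal) concentration, cells x 10^6/L.
#' @param measurements numeric vector of replicate measurements (length
#'   >= 2, finite, >= 0).
#' @return list of class `replicate_set`.
#' @export
replicate_set <- function(level_label, expected, measurements) {
  if (!is.numeric(measurements) || length(measurements) < 2)
    stop("replicate_set: need at least 2 measurements")
  if (!all(is.finite(measurements)) || any(measurements < 0))
    stop("replicate_set: measurements must be finite and >= 0")
  if (!is.finite(expected) || expected < 0)
    stop("replicate_set: expected must be finite and >= 0")
  structure(list(level_label = as.character(level_label), expected = expected,
                 measurements = as.numeric(measurements)),
            class = "replicate_set")
}

levels_table <- function(levels) {
  if (inherits(levels, "replicate_set")) levels <- list(levels)
  data.frame(
    level_label = vapply(levels, `[[`, character(1), "level_label"),
    expected = vapply(levels, `[[`, numeric(1), "expected"),
    mean = vapply(levels, function(l) mean(l$measurements), numeric(1)),
    sd = vapply(levels, function(l) sd(l$measurements), numeric(1)),
    n = vapply(levels, function(l) length(l$measurements), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Linearity of measured versus expected concentration
#'
#' Pearson correlation between the expected concentrations and the
#' per-level replicate means (pre-averaged values may be supplied directly
#' as a data.frame with columns `expected` and `measured`).
#'
#' @param levels list of [replicate_set()]s, or a data.frame with columns
#'   `expected`, `measured`.
#' @return object of class `linearity_result`: `r`, `r_squared`, `table`.
#' @export
linearity <- function(levels) {
  if (is.data.frame(levels)) {
    if (!all(c("expected", "measured") %in% names(levels)))
      stop("linearity: data.frame input needs columns 'expected' and 'measured'")
    tab <- data.frame(level_label = as.character(seq_len(nrow(levels))),
                      expected = levels$expected, mean = levels$measured,
                      sd = NA_real_, n = 1L)
  } else tab <- levels_table(levels)
  if (nrow(tab) < 3) stop("linearity: need at least 3 concentration levels")
  if (sd(tab$expected) == 0 || sd(tab$mean) == 0)
    stop("linearity: zero variance - correlation undefined")
  r <- cor(tab$expected, tab$mean)
  structure(list(r = r, r_squared = r^2, table = tab), class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("<linearity_result> r = %.4f, r^2 = %.4f over %d levels\n",
              x$r, x$r_squared, nrow(x$table)))
  invisible(x)
}

#' Limit of blank (nonparametric percentile)
#'
#' The CLSI nonparametric percentile of replicate measurements on
#' analyte-free samples: rank position `0.5 + (percentile/100) * N` with
#' linear interpolation between order statistics, clipped to the observed
#' range (this is `stats::quantile` type 5).
#'
#' @param blank_measurements numeric vector of blank-sample measurements.
#' @param percentile percentile, default 95.
#' @return the limit of blank (same units as the measurements).
#' @export
limit_of_blank <- function(blank_measurements, percentile = 95) {
  x <- blank_measurements
  if (length(x) == 0) stop("limit_of_blank: no blank measurements")
  if (!all(is.finite(x))) stop("limit_of_blank: measurements must be finite")
  if (length(x) < 20)
    warning("limit_of_blank: fewer than 20 blank measurements; the percentile is unstable")
  unname(quantile(x, percentile / 100, type = 5))
}

#' Limit of detection from replicate series
#'
#' For each level the exceedance fraction is the share of measurements
#' strictly greater than the limit of blank; the LOD is the smallest
#' expected concentration whose fraction exceeds 0.95 (strictly, so 19/20
#' does not qualify). When no level qualifies the LOD is undefined (`NA`)
#' and flagged.
#'
#' @param levels list of [replicate_set()]s (any order; sorted internally by
#'   expected concentration).
#' @param lob the limit of blank, from [limit_of_blank()].
#' @return object of class `loblod_result`: `lob`, `lod`, `defined`,
#'   `table` (per-level exceedance fractions).
#' @export
limit_of_detection <- function(levels, lob) {
  if (inherits(levels, "replicate_set")) levels <- list(levels)
  ord <- order(vapply(levels, `[[`, numeric(1), "expected"))
  levels <- levels[ord]
  tab <- levels_table(levels)
  if (any(tab$n < 20))
    warning("limit_of_detection: fewer than 20 replicates at some levels")
  tab$exceedance <- vapply(levels, function(l) mean(l$measurements > lob), numeric(1))
  qual <- tab$exceedance > 0.95
  lod <- if (any(qual)) tab$expected[which(qual)[1]] else NA_real_
  if (!is.na(lod) && lod < lob) lod <- lob  # LOD can never undercut the LOB
  structure(list(lob = lob, lod = lod, defined = !is.na(lod), table = tab),
            class = "loblod_result")
}

#' @export
print.loblod_result <- function(x, ...) {
  cat(sprintf("<loblod_result> LOB = %.4g; LOD = %s\n", x$lob,
              if (x$defined) sprintf("%.4g", x$lod) else "undefined"))
  invisible(x)
}

#' Precision profile (mean, SD, CV%) per level
#'
#' Sample SD uses the n-1 denominator; CV% = 100 * SD / mean, flagged
#' undefined (`NA`) when the level mean is zero.
#'
#' @param levels list of [replicate_set()]s.
#' @return object of class `precision_result` with a per-level `table`
#'   (`level_label`, `expected`, `mean`, `sd`, `cv_percent`, `n`).
#' @export
precision_profile <- function(levels) {
  tab <- levels_table(levels)
  tab$cv_percent <- ifelse(tab$mean == 0, NA_real_, 100 * tab$sd / tab$mean)
  structure(list(table = tab), class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat("<precision_result>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
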
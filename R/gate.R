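#' Gate thresholds for the two fluorescence channels
#'
#' Cuts dividing the (CF, GF) intensity plane into the four dot-plot zones:
#' C1 double-negative, C2 GF-positive (WBC), C3 CF-positive (RBC), C4
#' double-positive. Events exactly on a cut fall to the non-positive side
#' (`<=` convention), making zone assignment a total function.
#'
#' @param gf_cut,cf_cut intensity cuts (background-corrected units).
#' @param mode `"fixed"` (cuts supplied) or `"auto"` (recomputed per event
#'   set by [auto_threshold()]).
#' @return list of class `gate_thresholds`.
#' @export
gate_thresholds <- function(gf_cut = 100, cf_cut = 100, mode = c("fixed", "auto")) {
  mode <- match.arg(mode)
  if (!is.finite(gf_cut) || !is.finite(cf_cut)) stop("gate_thresholds: cuts must be finite")
  structure(list(gf_cut = gf_cut, cf_cut = cf_cut, mode = mode, fallback = FALSE),
            class = "gate_thresholds")
}

# Exact Otsu threshold of a numeric vector: exhaustive search over midpoints
# between consecutive sorted unique values for the split maximizing
# between-class variance. Returns NA when degenerate (fewer than 2 distinct
# values or no variance).
otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  u <- unique(x)
  if (length(u) < 2) return(NA_real_)
  n <- length(x)
  cs <- cumsum(x); tot <- cs[n]
  # candidate splits: after each position where the value changes
  pos <- which(diff(x) > 0)
  w1 <- pos / n
  m1 <- cs[pos] / pos
  m2 <- (tot - cs[pos]) / (n - pos)
  bcv <- w1 * (1 - w1) * (m1 - m2)^2
  k <- pos[which.max(bcv)]
  (x[k] + x[k + 1]) / 2
}

#' Automatic gate thresholds from an event set
#'
#' Per channel, the cut is the Otsu threshold computed on `log1p` of the
#' non-negative intensities (the log compresses the bright-signal tail so the
#' background/signal split dominates). When Otsu is degenerate (no intensity
#' spread), the cut falls back to the median of the positive intensities and
#' the result is flagged `fallback = TRUE`.
#'
#' @param events data.frame with `gf_intensity`, `cf_intensity`.
#' @param min_events minimum number of usable events.
#' @return a [gate_thresholds()] with `mode = "auto"`.
#' @export
auto_threshold <- function(events, min_events = 10L) {
  gf <- events$gf_intensity; cf <- events$cf_intensity
  ok <- is.finite(gf) & is.finite(cf)
  if (sum(ok) < min_events)
    stop("auto_threshold: fewer than ", min_events,
         " usable events; supply fixed thresholds instead")
  one <- function(x) {
    lx <- log1p(pmax(x, 0))
    cut_l <- otsu_threshold(lx)
    if (is.na(cut_l) || cut_l <= 0) {
      pos <- x[x > 0]
      cut <- if (length(pos)) median(pos) else 0
      list(cut = cut, fb = TRUE)
    } else list(cut = expm1(cut_l), fb = FALSE)
  }
  g <- one(gf[ok]); c_ <- one(cf[ok])
  th <- gate_thresholds(g$cut, c_$cut, mode = "auto")
  th$fallback <- g$fb || c_$fb
  th
}

#' Assign dot-plot zones to events
#'
#' @param events data.frame with `gf_intensity`, `cf_intensity`.
#' @param thresholds a resolved [gate_thresholds()] (fixed cuts).
#' @return list with `zone` (factor `C1`–`C4`, `NA` for non-finite events),
#'   `counts` (named zone counts), `invalid` (number of excluded events), and
#'   `thresholds_used`.
#' @export
assign_zones <- function(events, thresholds) {
  gf <- events$gf_intensity; cf <- events$cf_intensity
  ok <- is.finite(gf) & is.finite(cf)
  zone <- rep(NA_character_, length(gf))
  gp <- gf > thresholds$gf_cut; cp <- cf > thresholds$cf_cut
  zone[ok & !gp & !cp] <- "C1"
  zone[ok & gp & !cp]  <- "C2"
  zone[ok & !gp & cp]  <- "C3"
  zone[ok & gp & cp]   <- "C4"
  zone <- factor(zone, levels = c("C1", "C2", "C3", "C4"))
  list(zone = zone, counts = table(zone), invalid = sum(!ok),
       thresholds_used = thresholds)
}

#' Rules for resolving the double-positive (C4) zone
#'
#' Deterministic stand-in for image-level review of double-positive events.
#' Rule order for a C4 event of radius r (um): a doublet band
#' `(doublet_factor, doublet_max_factor] x` the largest single-cell radius is
#' checked first (an event there is an overlapping WBC+RBC pair and
#' contributes one count to each class); outside that band, a radius not in
#' either class interval is an artifact; otherwise the event goes to the
#' class with the larger cut-normalized intensity (`gf/gf_cut` vs
#' `cf/cf_cut`), exact ties to artifact.
#'
#' @param wbc_radius_um,rbc_radius_um class radius intervals (um).
#' @param pixel_size_um pixel pitch.
#' @param doublet_factor,doublet_max_factor doublet band, in multiples of the
#'   largest single-cell radius.
#' @return list of class `c4_rules`.
#' @export
c4_rules <- function(wbc_radius_um = c(3.5, 6), rbc_radius_um = c(2.5, 4),
                     pixel_size_um = 1, doublet_factor = 1.5,
                     doublet_max_factor = 2.2) {
  if (doublet_max_factor <= doublet_factor)
    stop("c4_rules: doublet_max_factor must exceed doublet_factor")
  structure(list(wbc_radius_um = wbc_radius_um, rbc_radius_um = rbc_radius_um,
                 pixel_size_um = pixel_size_um, doublet_factor = doublet_factor,
                 doublet_max_factor = doublet_max_factor),
            class = "c4_rules")
}

#' Resolve double-positive events
#'
#' @param c4_events data.frame with `radius_px`, `gf_intensity`,
#'   `cf_intensity` for the events assigned to C4.
#' @param rules a [c4_rules()].
#' @param thresholds the [gate_thresholds()] used for zoning (the intensity
#'   ratio is normalized by the cuts).
#' @return character vector, one of `"WBC"`, `"RBC"`, `"DOUBLET"`,
#'   `"ARTIFACT"` per event.
#' @export
resolve_c4 <- function(c4_events, rules, thresholds) {
  n <- nrow(c4_events)
  if (n == 0) return(character(0))
  r_um <- c4_events$radius_px * rules$pixel_size_um
  rmax <- max(rules$wbc_radius_um[2], rules$rbc_radius_um[2])
  in_class <- (r_um >= rules$wbc_radius_um[1] & r_um <= rules$wbc_radius_um[2]) |
              (r_um >= rules$rbc_radius_um[1] & r_um <= rules$rbc_radius_um[2])
  out <- character(n)
  rw <- c4_events$gf_intensity / thresholds$gf_cut
  rr <- c4_events$cf_intensity / thresholds$cf_cut
  for (i in seq_len(n)) {
    out[i] <- if (r_um[i] > rules$doublet_factor * rmax &&
                  r_um[i] <= rules$doublet_max_factor * rmax) "DOUBLET"
    else if (!in_class[i]) "ARTIFACT"
    else if (rw[i] > rr[i]) "WBC"
    else if (rr[i] > rw[i]) "RBC"
    else "ARTIFACT"
  }
  out
}

#' Gate an event set end to end
#'
#' Resolves thresholds (auto mode recomputes them from the events), assigns
#' zones, resolves the C4 overlap zone, and produces adjusted class counts.
#' `artifact_count` comprises double-negative (C1) events and C4 events
#' resolved as artifacts; each doublet adds one count to *both* classes, so
#' `adjusted_wbc + adjusted_rbc + artifact_count - doublet_count` equals the
#' number of gated events.
#'
#' @param events detections with intensities (see [measure_intensities()]).
#' @param thresholds a [gate_thresholds()]; auto mode triggers
#'   [auto_threshold()].
#' @param rules a [c4_rules()].
#' @return object of class `gate_result`: `zone`, `attribution`, `counts`,
#'   `adjusted_wbc`, `adjusted_rbc`, `artifact_count`, `doublet_count`,
#'   `invalid`, `thresholds_used`.
#' @export
gate_events <- function(events, thresholds = gate_thresholds(), rules = c4_rules()) {
  if (identical(thresholds$mode, "auto")) thresholds <- auto_threshold(events)
  za <- assign_zones(events, thresholds)
  zone <- za$zone
  attribution <- rep(NA_character_, length(zone))
  is_c4 <- !is.na(zone) & zone == "C4"
  if (any(is_c4))
    attribution[is_c4] <- resolve_c4(events[is_c4, , drop = FALSE], rules, thresholds)
  cnt <- as.integer(za$counts)
  names(cnt) <- names(za$counts)
  doublets <- sum(attribution == "DOUBLET", na.rm = TRUE)
  res <- structure(list(
    zone = zone, attribution = attribution, counts = cnt,
    adjusted_wbc = cnt[["C2"]] + sum(attribution %in% c("WBC", "DOUBLET")),
    adjusted_rbc = cnt[["C3"]] + sum(attribution %in% c("RBC", "DOUBLET")),
    artifact_count = cnt[["C1"]] + sum(attribution == "ARTIFACT", na.rm = TRUE),
    doublet_count = doublets, invalid = za$invalid,
    thresholds_used = thresholds
  ), class = "gate_result")
  res
}

#' @export
print.gate_result <- function(x, ...) {
  cat("<gate_result>\n  zones:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  cat(sprintf("  adjusted WBC %d, RBC %d; artifacts %d (doublets %d, invalid %d)\n",
              x$adjusted_wbc, x$adjusted_rbc, x$artifact_count,
              x$doublet_count, x$invalid))
  cat(sprintf("  cuts: gf %.4g, cf %.4g (%s)\n", x$thresholds_used$gf_cut,
              x$thresholds_used$cf_cut, x$thresholds_used$mode))
  invisible(x)
}

#' Histogram summary of a gated event set
#'
#' The G1 region count equals the adjusted WBC count and G2 the adjusted RBC
#' count; per-channel binned distributions of `log1p` intensity are returned
#' with their bin edges.
#'
#' @param gate_result a [gate_events()] result.
#' @param events the event set that was gated.
#' @param n_bins number of histogram bins per channel.
#' @return list `g1_count`, `g2_count`, `gf_hist`, `cf_hist` (each with
#'   `breaks` and `counts`).
#' @export
build_histogram <- function(gate_result, events, n_bins = 64L) {
  one <- function(x) {
    x <- log1p(pmax(x[is.finite(x)], 0))
    if (length(x) == 0) return(list(breaks = numeric(0), counts = integer(0)))
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  list(g1_count = gate_result$adjusted_wbc,
       g2_count = gate_result$adjusted_rbc,
       gf_hist = one(events$gf_intensity),
       cf_hist = one(events$cf_intensity))
}
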
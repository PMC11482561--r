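#' Circle detector configuration
#'
#' Parameters of the gradient-voting circle Hough transform. The radius range
#' is in pixels; [filter_by_size()] applies the biological size gate in
#' micrometres afterwards.
#'
#' @param radius_min_px,radius_max_px integer radius search range (pixels).
#' @param edge_threshold gradient-magnitude threshold (intensity units/px)
#'   above which a pixel votes.
#' @param accumulator_threshold minimum normalized vote score (votes per unit
#'   circumference) for a peak to be reported. A soft-edged disc rim
#'   contributes two concentric gradient rings, so true cells score about 2;
#'   rim ghosts stay below 1. The default 1.2 separates the two.
#' @param nms_min_distance_px minimum center distance kept by non-maximum
#'   suppression.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(radius_min_px = 2L, radius_max_px = 9L,
                            edge_threshold = 60, accumulator_threshold = 1.2,
                            nms_min_distance_px = 5) {
  if (radius_min_px < 1 || radius_max_px < radius_min_px)
    stop("detector_config: need 0 < radius_min_px <= radius_max_px")
  if (edge_threshold < 0 || accumulator_threshold < 0 || nms_min_distance_px < 0)
    stop("detector_config: thresholds must be >= 0")
  structure(list(radius_min_px = as.integer(radius_min_px),
                 radius_max_px = as.integer(radius_max_px),
                 edge_threshold = edge_threshold,
                 accumulator_threshold = accumulator_threshold,
                 nms_min_distance_px = nms_min_distance_px),
            class = "detector_config")
}

# Central-difference gradients; borders zero. Returns list(gx, gy).
image_gradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  if (w >= 3) gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  if (h >= 3) gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# 3x3 box sum of a matrix (zero-padded) via shift-adds.
box_sum3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  z <- rep(0, w)
  v <- m + rbind(z, m[-h, , drop = FALSE]) + rbind(m[-1, , drop = FALSE], z)
  zc <- rep(0, h)
  v + cbind(zc, v[, -w, drop = FALSE]) + cbind(v[, -1, drop = FALSE], zc)
}

#' Detect circles in a raster by gradient-voting Hough transform
#'
#' Thresholds the gradient magnitude at `edge_threshold`; each edge pixel
#' casts votes along plus/minus its gradient direction at every radius in the
#' configured range; the per-radius accumulators are consolidated with a 3x3
#' box sum and normalized by circumference (`2 pi r`), so a fully supported
#' circle scores about 1 regardless of radius. Local maxima of the
#' best-over-radius score above `accumulator_threshold` are reported after
#' greedy non-maximum suppression (higher score kept; ties broken by smaller
#' `(y, x)`). The radius estimate is the vote-weighted mean radius within one
#' step of the per-center best radius. Deterministic given inputs.
#'
#' Coordinates are 0-based, `x` = column, `y` = row.
#'
#' @param image numeric matrix.
#' @param config a [detector_config()].
#' @return data.frame `x`, `y`, `radius_px`, `score`, ordered by the NMS
#'   (descending score).
#' @export
detect_circles <- function(image, config = detector_config()) {
  if (!is.matrix(image) || length(image) == 0) stop("detect_circles: image must be a non-empty matrix")
  if (!inherits(config, "detector_config")) stop("detect_circles: config must be a detector_config")
  h <- nrow(image); w <- ncol(image)
  if (2 * config$radius_max_px >= min(h, w))
    stop("detect_circles: radius range [", config$radius_min_px, ", ",
         config$radius_max_px, "] px does not fit the ", w, " x ", h, " image")
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      radius_px = numeric(0), score = numeric(0))

  g <- image_gradient(image)
  mag <- sqrt(g$gx^2 + g$gy^2)
  edge <- which(mag > config$edge_threshold)
  if (length(edge) == 0) return(empty)
  ey <- (edge - 1) %% h        # 0-based row (y)
  ex <- (edge - 1) %/% h       # 0-based col (x)
  ux <- g$gx[edge] / mag[edge]
  uy <- g$gy[edge] / mag[edge]

  radii <- config$radius_min_px:config$radius_max_px
  nr <- length(radii)
  acc <- vector("list", nr)
  for (k in seq_len(nr)) {
    r <- radii[k]
    votes <- integer(h * w)
    for (s in c(-1, 1)) {
      cx <- round(ex + s * r * ux); cy <- round(ey + s * r * uy)
      ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
      if (any(ok)) {
        idx <- cx[ok] * h + cy[ok] + 1
        votes <- votes + tabulate(idx, nbins = h * w)
      }
    }
    acc[[k]] <- box_sum3(matrix(votes, h, w)) / (2 * pi * r)
  }

  score <- acc[[1]]; best_k <- matrix(1L, h, w)
  if (nr > 1) for (k in 2:nr) {
    better <- acc[[k]] > score
    score[better] <- acc[[k]][better]
    best_k[better] <- k
  }

  cand <- which(score > config$accumulator_threshold)
  if (length(cand) == 0) return(empty)
  # strict-on-later-neighbors local maxima: >= all 8 neighbors, and strictly >
  # neighbors that precede in (y, x) order would keep plateau duplicates; NMS
  # resolves those, so plain >= is sufficient here.
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    id <- cand[i]
    y <- (id - 1) %% h; x <- (id - 1) %/% h
    ys <- max(0, y - 1):min(h - 1, y + 1)
    xs <- max(0, x - 1):min(w - 1, x + 1)
    keep[i] <- score[id] >= max(score[ys + 1, xs + 1])
  }
  cand <- cand[keep]
  if (length(cand) == 0) return(empty)

  cy <- (cand - 1) %% h; cx <- (cand - 1) %/% h
  sc <- score[cand]
  # radius: vote-weighted mean over best_k +/- 1 (votes, i.e. score * 2 pi r)
  rad <- vapply(seq_along(cand), function(i) {
    k0 <- best_k[cand[i]]
    ks <- max(1, k0 - 1):min(nr, k0 + 1)
    wts <- vapply(ks, function(k) acc[[k]][cand[i]] * 2 * pi * radii[k], numeric(1))
    sum(wts * radii[ks]) / sum(wts)
  }, numeric(1))

  ord <- order(-sc, cy, cx)
  cx <- cx[ord]; cy <- cy[ord]; sc <- sc[ord]; rad <- rad[ord]
  taken <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (i == 1) { taken[1] <- TRUE; next }
    j <- which(taken)
    if (all((cx[j] - cx[i])^2 + (cy[j] - cy[i])^2 >= config$nms_min_distance_px^2))
      taken[i] <- TRUE
  }
  data.frame(x = cx[taken], y = cy[taken], radius_px = rad[taken], score = sc[taken])
}

#' Filter detections by physical size
#'
#' Keeps exactly the detections whose radius, converted to micrometres, lies
#' in the closed interval `radius_range_um`. Order is preserved.
#'
#' @param detections data.frame with a `radius_px` column.
#' @param radius_range_um closed interval `c(lo, hi)` in micrometres.
#' @param pixel_size_um pixel pitch, micrometres.
#' @return the filtered data.frame.
#' @export
filter_by_size <- function(detections, radius_range_um, pixel_size_um) {
  if (pixel_size_um <= 0) stop("filter_by_size: pixel_size_um must be > 0")
  if (length(radius_range_um) != 2 || radius_range_um[1] > radius_range_um[2])
    stop("filter_by_size: radius_range_um must be a non-empty [lo, hi]")
  r_um <- detections$radius_px * pixel_size_um
  detections[r_um >= radius_range_um[1] & r_um <= radius_range_um[2], , drop = FALSE]
}

#' Measure background-corrected disc intensities
#'
#' For each detection and each fluorescence channel: intensity = mean over
#' the detection disc minus the median over a concentric background annulus
#' (inner radius `r + 2` px, width 3 px). Annulus pixels covered by any other
#' detection's disc are excluded so neighbors do not inflate the background.
#' Discs extending beyond the raster are clipped and flagged `edge`.
#'
#' @param detections data.frame from [detect_circles()].
#' @param gf_raster,cf_raster fluorescence rasters.
#' @return `detections` with columns `gf_intensity`, `cf_intensity`, `edge`
#'   added. Background-corrected intensities may be negative.
#' @export
measure_intensities <- function(detections, gf_raster, cf_raster) {
  if (!identical(dim(gf_raster), dim(cf_raster)))
    stop("measure_intensities: rasters must share dimensions")
  h <- nrow(gf_raster); w <- ncol(gf_raster)
  n <- nrow(detections)
  gf_i <- cf_i <- numeric(n); edge <- logical(n)
  if (n == 0) {
    detections$gf_intensity <- numeric(0); detections$cf_intensity <- numeric(0)
    detections$edge <- logical(0)
    return(detections)
  }
  # occupancy count of detection discs, for annulus exclusion
  occ <- matrix(0L, h, w)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- detections$x[i]; cy <- detections$y[i]; r <- detections$radius_px[i]
    x0 <- max(0, floor(cx - r - 5)); x1 <- min(w - 1, ceiling(cx + r + 5))
    y0 <- max(0, floor(cy - r - 5)); y1 <- min(h - 1, ceiling(cy + r + 5))
    xs <- x0:x1; ys <- y0:y1
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
    masks[[i]] <- list(xs = xs, ys = ys, d = d)
    disc <- d <= r
    occ[ys + 1, xs + 1] <- occ[ys + 1, xs + 1] + disc
    edge[i] <- (cx - r < 0) || (cx + r > w - 1) || (cy - r < 0) || (cy + r > h - 1)
  }
  for (i in seq_len(n)) {
    m <- masks[[i]]; r <- detections$radius_px[i]
    sub_occ <- occ[m$ys + 1, m$xs + 1]
    disc <- m$d <= r
    ann <- m$d >= r + 2 & m$d <= r + 5 & sub_occ == 0L
    if (!any(ann)) ann <- m$d >= r + 2 & m$d <= r + 5  # fully surrounded: fall back
    for (ch in c("gf", "cf")) {
      ras <- if (ch == "gf") gf_raster else cf_raster
      sub <- ras[m$ys + 1, m$xs + 1]
      val <- mean(sub[disc]) - median(sub[ann])
      if (ch == "gf") gf_i[i] <- val else cf_i[i] <- val
    }
  }
  detections$gf_intensity <- gf_i
  detections$cf_intensity <- cf_i
  detections$edge <- edge
  detections
}

#' Run detection and intensity measurement on one field
#'
#' Convenience wrapper: detects circles on the summed fluorescence raster
#' (`gf + cf`, where every stained object is bright), applies the size gate,
#' and measures per-channel intensities.
#'
#' @param field a [field_image()].
#' @param config a [detector_config()].
#' @param radius_range_um size gate in micrometres (`NULL` to skip).
#' @return detections data.frame with intensities.
#' @export
detect_field <- function(field, config = detector_config(),
                         radius_range_um = c(2, 7)) {
  det <- detect_circles(field$gf + field$cf, config)
  if (!is.null(radius_range_um))
    det <- filter_by_size(det, radius_range_um, field$pixel_size_um)
  measure_intensities(det, field$gf, field$cf)
}
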
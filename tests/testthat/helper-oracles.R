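# Independent oracles and small fixture builders used across the suite.

# Literal Passing-Bablok enumerator: explicit double loop over pairs, explicit
# median arithmetic on the sorted slope list with the offset-K shift. Kept
# deliberately loop-based and separate from the package implementation.
pb_bruteforce <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) slopes <- c(slopes, s)
      }
    }
  }
  if (length(slopes) == 0) stop("no valid slopes")
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- 0
  for (s in slopes) if (s < -1) K <- K + 1
  pick <- function(i) slopes[min(max(i, 1), N)]
  b <- if (N %% 2 == 1) pick((N + 1) / 2 + K) else (pick(N / 2 + K) + pick(N / 2 + 1 + K)) / 2
  resid <- c()
  for (i in seq_len(n)) resid <- c(resid, y[i] - b * x[i])
  list(slope = b, intercept = median(resid))
}

# Brute-force best-circle search: recomputes an edge map with simple loops and
# scores every integer (cx, cy, r) by the fraction of perimeter samples that
# land on an edge pixel. Returns the global best circle. Only for tiny images.
circle_bruteforce <- function(img, edge_threshold, r_range) {
  h <- nrow(img); w <- ncol(img)
  mag <- matrix(0, h, w)
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    gx <- (img[i, j + 1] - img[i, j - 1]) / 2
    gy <- (img[i + 1, j] - img[i - 1, j]) / 2
    mag[i, j] <- sqrt(gx^2 + gy^2)
  }
  edge <- mag > edge_threshold
  best <- list(score = -1)
  for (r in r_range[1]:r_range[2]) {
    th <- seq(0, 2 * pi, length.out = max(16, ceiling(4 * pi * r)) + 1)[-1]
    dx <- round(r * cos(th)); dy <- round(r * sin(th))
    for (cy in r:(h - 1 - r)) for (cx in r:(w - 1 - r)) {
      px <- cx + dx; py <- cy + dy
      sc <- mean(edge[cbind(py + 1, px + 1)])
      if (sc > best$score) best <- list(score = sc, x = cx, y = cy, r = r)
    }
  }
  best
}

# Greedy one-to-one matching of detections to ground-truth objects within a
# distance tolerance; returns recall and precision.
match_detections <- function(det, truth, tol = 2) {
  if (nrow(truth) == 0) return(list(recall = 1, precision = if (nrow(det)) 0 else 1))
  if (nrow(det) == 0) return(list(recall = 0, precision = 1))
  used <- rep(FALSE, nrow(det))
  hit <- 0
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) { used[j] <- TRUE; hit <- hit + 1 }
  }
  list(recall = hit / nrow(truth), precision = sum(used) / nrow(det))
}

# A small raster containing one soft-edged disc, built directly (not via the
# generator) so detector tests do not depend on the generator.
disc_raster <- function(h, w, cx, cy, radius, amp, background = 100) {
  m <- matrix(background, h, w)
  for (i in 1:h) for (j in 1:w) {
    d <- sqrt((j - 1 - cx)^2 + (i - 1 - cy)^2)
    m[i, j] <- m[i, j] + amp * min(1, max(0, radius + 0.5 - d))
  }
  m
}

# Replicate sets with constructed values.
rs <- function(label, expected, values) replicate_set(label, expected, values)
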
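#' Construct a field image container
#'
#' Three co-registered intensity rasters (bright-field, green fluorescence,
#' cyan fluorescence) plus the pixel/volume metadata needed downstream.
#' Matrices are indexed `[row, col]`; coordinates elsewhere in the package are
#' 0-based with `x` = column and `y` = row, pixel centers at integer
#' coordinates.
#'
#' @param bf,gf,cf numeric matrices of identical dimensions, non-negative.
#' @param pixel_size_um,depth_um geometry, micrometres.
#' @param volume_nl imaged volume; if `NULL`, computed from the geometry.
#' @return object of class `field_image`.
#' @export
field_image <- function(bf, gf, cf, pixel_size_um, depth_um, volume_nl = NULL) {
  if (!identical(dim(bf), dim(gf)) || !identical(dim(bf), dim(cf)))
    stop("field_image: the three rasters must share dimensions")
  if (min(bf, gf, cf) < 0) stop("field_image: rasters must be non-negative")
  geom_v <- ncol(bf) * nrow(bf) * pixel_size_um^2 * depth_um * 1e-6
  if (is.null(volume_nl)) volume_nl <- geom_v
  if (abs(volume_nl - geom_v) > 1e-6 * geom_v)
    stop("field_image: volume_nl inconsistent with raster geometry")
  structure(list(bf = bf, gf = gf, cf = cf,
                 pixel_size_um = pixel_size_um, depth_um = depth_um,
                 volume_nl = volume_nl),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px, %.3g um/px, depth %.4g um, %.4f nL\n",
              ncol(x$bf), nrow(x$bf), x$pixel_size_um, x$depth_um, x$volume_nl))
  invisible(x)
}

# Add one soft-edged disc to a raster in place (returns modified matrix).
# Radial profile: amp * clamp(radius + 0.5 - d, 0, 1) -- a 1-px linear edge
# ramp so image gradients at the rim are well defined.
add_disc <- function(img, cx, cy, radius, amp) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(0, floor(cx - radius - 1)); x1 <- min(w - 1, ceiling(cx + radius + 1))
  y0 <- max(0, floor(cy - radius - 1)); y1 <- min(h - 1, ceiling(cy + radius + 1))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp * pmin(1, pmax(0, radius + 0.5 - d))
  img
}

# Rejection-sample a center at least `margin` from the border and (when
# overlap is disallowed) not closer than r_i + r_j + gap to earlier cells.
place_center <- function(w, h, radius, placed, overlap_allowed, gap = 2, max_try = 500) {
  lo_x <- radius + 2; hi_x <- w - 1 - radius - 2
  lo_y <- radius + 2; hi_y <- h - 1 - radius - 2
  if (hi_x <= lo_x || hi_y <= lo_y) stop("field too small for a cell of radius ", radius)
  for (i in seq_len(max_try)) {
    cx <- runif(1, lo_x, hi_x); cy <- runif(1, lo_y, hi_y)
    if (overlap_allowed || nrow(placed) == 0L) return(c(cx, cy))
    if (all(sqrt((placed$x - cx)^2 + (placed$y - cy)^2) >
            placed$radius_px + radius + gap)) return(c(cx, cy))
  }
  c(cx, cy)  # crowded field: accept the last draw
}

#' Render one synthetic chip field with ground truth
#'
#' Draws Poisson cell numbers per class with mean `conc * volume_nl / 1000`,
#' places soft-edged discs (WBCs bright in GF, RBCs bright in CF, both faintly
#' visible in BF), optionally adds debris/aggregate artifacts, and applies
#' additive Gaussian noise. The returned ground truth lists every rendered
#' object exactly.
#'
#' Artifacts come in three kinds, mirroring what contaminates real chip
#' images: sub-cellular debris (radius below the cell range), large
#' aggregates (radius well above the doublet range), and ambiguous specks
#' (cell-sized but equally bright in both channels).
#'
#' @param spec a [field_spec()].
#' @return list with elements `image` (a [field_image()]) and `truth`
#'   (a data.frame `class`, `x`, `y`, `radius_px`, `gf_amp`, `cf_amp`, plus
#'   attributes `true_wbc_count`, `true_rbc_count`).
#' @export
render_field <- function(spec) {
  if (!inherits(spec, "field_spec")) stop("render_field: spec must be a field_spec")
  with_seed(spec$seed, {
    w <- spec$width_px; h <- spec$height_px; ps <- spec$pixel_size_um
    vol <- field_volume_nl(spec)
    n_wbc <- rpois(1, spec$wbc_conc * vol / 1000)
    n_rbc <- rpois(1, spec$rbc_conc * vol / 1000)
    n_art <- if (spec$artifact_rate > 0) rpois(1, spec$artifact_rate) else 0L

    truth <- data.frame(class = character(0), x = numeric(0), y = numeric(0),
                        radius_px = numeric(0), gf_amp = numeric(0), cf_amp = numeric(0),
                        stringsAsFactors = FALSE)
    im <- spec$intensity_model
    draw_amp <- function(p) c(rlnorm(1, p$gf_meanlog, p$gf_sdlog),
                              rlnorm(1, p$cf_meanlog, p$cf_sdlog))
    for (i in seq_len(n_wbc)) {
      r <- runif(1, spec$wbc_radius_um[1], spec$wbc_radius_um[2]) / ps
      c0 <- place_center(w, h, r, truth, spec$overlap_allowed)
      a <- draw_amp(im$wbc)
      truth[nrow(truth) + 1L, ] <- list("WBC", c0[1], c0[2], r, a[1], a[2])
    }
    for (i in seq_len(n_rbc)) {
      r <- runif(1, spec$rbc_radius_um[1], spec$rbc_radius_um[2]) / ps
      c0 <- place_center(w, h, r, truth, spec$overlap_allowed)
      a <- draw_amp(im$rbc)
      truth[nrow(truth) + 1L, ] <- list("RBC", c0[1], c0[2], r, a[1], a[2])
    }
    r_cell_px <- range(spec$wbc_radius_um, spec$rbc_radius_um) / ps
    for (i in seq_len(n_art)) {
      kind <- sample(c("debris", "aggregate", "speck"), 1)
      if (kind == "debris") {
        r <- runif(1, 0.3, 0.7) * r_cell_px[1]
        amp <- runif(1, 100, 600); a <- c(amp, amp * runif(1, 0.2, 0.8))
      } else if (kind == "aggregate") {
        r <- runif(1, 2.4, 3.2) * r_cell_px[2]
        amp <- runif(1, 200, 800); a <- c(amp, amp)
      } else {
        r <- runif(1, r_cell_px[1], r_cell_px[2])
        amp <- runif(1, 300, 900); a <- c(amp, amp)
      }
      c0 <- place_center(w, h, r, truth, spec$overlap_allowed)
      truth[nrow(truth) + 1L, ] <- list("ARTIFACT", c0[1], c0[2], r, a[1], a[2])
    }

    base <- function() {
      m <- matrix(rnorm(h * w, spec$background_level, spec$noise_sd), h, w)
      m[m < 0] <- 0
      m
    }
    bf <- base(); gf <- base(); cf <- base()
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      gf <- add_disc(gf, tr$x, tr$y, tr$radius_px, tr$gf_amp)
      cf <- add_disc(cf, tr$x, tr$y, tr$radius_px, tr$cf_amp)
      bf <- add_disc(bf, tr$x, tr$y, tr$radius_px, 0.1 * max(tr$gf_amp, tr$cf_amp))
    }
    attr(truth, "true_wbc_count") <- n_wbc
    attr(truth, "true_rbc_count") <- n_rbc
    list(image = field_image(bf, gf, cf, ps, spec$depth_um, vol), truth = truth)
  })
}

#' Simulate one measured sample as a set of chip fields
#'
#' Emulates loading a stained sample onto the chip: the sample concentrations
#' are divided by the staining and sample dilution factors (that is the
#' concentration actually inside the chip), `n_fields` fields are rendered
#' with per-field seeds derived from `seed`, and fields plus pooled ground
#' truth are returned. [run_count()]/[count_fields()] undo the dilution when
#' converting counts back to a sample concentration.
#'
#' @param wbc_conc,rbc_conc sample concentrations, cells x 10^6/L.
#' @param n_fields number of fields imaged (default 42, which images
#'   42 x 23.8144 nL, about 1 uL).
#' @param dilution a [dilution_spec()].
#' @param spec base [field_spec()]; its concentrations and seed are
#'   overridden.
#' @param seed master seed for the per-field streams.
#' @return list `fields` (list of `field_image`), `truths` (list),
#'   `true_wbc`, `true_rbc` (total rendered cells over all fields).
#' @export
simulate_sample <- function(wbc_conc, rbc_conc = 0, n_fields = 42L,
                            dilution = dilution_spec(), spec = field_spec(),
                            seed = 1L) {
  dil <- stain_dilution_factor(dilution) * dilution$sample_dilution_factor
  fields <- vector("list", n_fields); truths <- vector("list", n_fields)
  for (k in seq_len(n_fields)) {
    sp <- spec
    sp$wbc_conc <- wbc_conc / dil
    sp$rbc_conc <- rbc_conc / dil
    sp$seed <- derive_seed(seed, k)
    out <- render_field(sp)
    fields[[k]] <- out$image; truths[[k]] <- out$truth
  }
  list(fields = fields, truths = truths,
       true_wbc = sum(vapply(truths, attr, integer(1), "true_wbc_count")),
       true_rbc = sum(vapply(truths, attr, integer(1), "true_rbc_count")))
}

#' Write / read a field as multi-page TIFF with a JSON sidecar
#'
#' Fields are stored as 16-bit multi-page TIFF (page order BF, GF, CF) plus a
#' `.json` sidecar carrying the geometry and, when supplied, the ground
#' truth. Intensities above 65535 are clipped on write.
#'
#' @param field a [field_image()].
#' @param path output path (`.tif`); the sidecar is written next to it.
#' @param truth optional ground-truth data.frame from [render_field()].
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, truth = NULL) {
  pages <- lapply(field[c("bf", "gf", "cf")], function(m) pmin(m, 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = field$pixel_size_um, depth_um = field$depth_um,
               volume_nl = field$volume_nl)
  if (!is.null(truth)) {
    meta$truth <- truth
    meta$true_wbc_count <- attr(truth, "true_wbc_count")
    meta$true_rbc_count <- attr(truth, "true_rbc_count")
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname write_field
#' @param pixel_size_um,depth_um geometry overrides used when no sidecar is
#'   present (required for bare PNG input).
#' @details `read_field()` accepts either a multi-page TIFF or a vector of
#'   three single-channel PNG paths in BF, GF, CF order.
#' @export
read_field <- function(path, pixel_size_um = NULL, depth_um = NULL) {
  if (length(path) == 3L) {
    pages <- lapply(path, function(p) {
      m <- png::readPNG(p)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 3L) stop("read_field: expected 3 pages (BF, GF, CF) in ", path)
  }
  sc <- sidecar_path(path[1])
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
  ps <- pixel_size_um %||% meta$pixel_size_um
  dp <- depth_um %||% meta$depth_um
  if (is.null(ps) || is.null(dp))
    stop("read_field: pixel_size_um/depth_um not in sidecar; pass them explicitly")
  pages <- lapply(pages, function(m) m * 65535)
  field_image(pages[[1]], pages[[2]], pages[[3]], ps, dp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
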
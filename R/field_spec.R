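#' Per-class fluorescence intensity model
#'
#' Log-normal amplitude parameters for the green-fluorescence (GF) and
#' cyan-fluorescence (CF) signal of each cell class. WBCs (nucleic-acid
#' stained) are bright in GF and near background in CF; RBCs (surface-antibody
#' stained) are the reverse. Amplitudes are in the same arbitrary units as the
#' raster background.
#'
#' @param wbc,rbc named lists with elements `gf_meanlog`, `gf_sdlog`,
#'   `cf_meanlog`, `cf_sdlog` (log-normal parameters of the peak amplitude).
#' @return list of class `intensity_model`.
#' @export
intensity_model <- function(wbc = list(gf_meanlog = log(1000), gf_sdlog = 0.25,
                                       cf_meanlog = log(10),   cf_sdlog = 0.5),
                            rbc = list(gf_meanlog = log(10),   gf_sdlog = 0.5,
                                       cf_meanlog = log(800),  cf_sdlog = 0.25)) {
  need <- c("gf_meanlog", "gf_sdlog", "cf_meanlog", "cf_sdlog")
  for (cls in list(wbc, rbc)) {
    if (!all(need %in% names(cls)) || !all(vapply(cls[need], is.finite, logical(1))))
      stop("intensity_model: each class needs finite ", paste(need, collapse = ", "))
  }
  structure(list(wbc = wbc, rbc = rbc), class = "intensity_model")
}

#' Specification of one imaged chip section
#'
#' Describes the geometry, cell content and noise of a single imaged field of
#' the counting chip. The default geometry (488 x 488 px at 1 um/px over a
#' 100 um deep channel) images exactly 23.8144 nL per field, the volume per
#' image of the chip imager this package models.
#'
#' Concentrations are those of the fluid *inside the chip* (i.e. after any
#' staining dilution), in cells x 10^6/L = cells/uL. The expected number of
#' cells per field is `conc * volume_nl / 1000`; per-field counts are Poisson.
#'
#' @param width_px,height_px raster size in pixels.
#' @param pixel_size_um pixel pitch in micrometres.
#' @param depth_um depth of the microfluidic channel in micrometres.
#' @param wbc_conc,rbc_conc in-chip concentrations, cells x 10^6/L.
#' @param wbc_radius_um,rbc_radius_um closed radius intervals (um) from which
#'   cell radii are drawn uniformly. The intervals may overlap.
#' @param intensity_model see [intensity_model()].
#' @param background_level,noise_sd additive background level and Gaussian
#'   noise standard deviation (arbitrary intensity units).
#' @param artifact_rate expected number of debris/aggregate artifacts per
#'   field (Poisson).
#' @param overlap_allowed if `FALSE` (default) cells are placed with rejection
#'   sampling so discs do not touch.
#' @param seed optional integer seed making the rendered field reproducible.
#' @return list of class `field_spec`.
#' @examples
#' sp <- field_spec(wbc_conc = 420)
#' field_volume_nl(sp)            # 23.8144
#' 420 * field_volume_nl(sp) / 1000  # expected WBCs per field, ~10
#' @export
field_spec <- function(width_px = 488L, height_px = 488L,
                       pixel_size_um = 1, depth_um = 100,
                       wbc_conc = 0, rbc_conc = 0,
                       wbc_radius_um = c(3.5, 6),
                       rbc_radius_um = c(2.5, 4),
                       intensity_model = csfscan::intensity_model(),
                       background_level = 100, noise_sd = 5,
                       artifact_rate = 0, overlap_allowed = FALSE,
                       seed = NULL) {
  num_ok <- function(x, n = 1) is.numeric(x) && length(x) == n && all(is.finite(x))
  if (!num_ok(width_px) || !num_ok(height_px) || width_px < 8 || height_px < 8)
    stop("field_spec: width_px and height_px must be finite and >= 8")
  if (!num_ok(pixel_size_um) || pixel_size_um <= 0) stop("field_spec: pixel_size_um must be > 0")
  if (!num_ok(depth_um) || depth_um <= 0) stop("field_spec: depth_um must be > 0")
  if (!num_ok(wbc_conc) || wbc_conc < 0) stop("field_spec: wbc_conc must be finite and >= 0")
  if (!num_ok(rbc_conc) || rbc_conc < 0) stop("field_spec: rbc_conc must be finite and >= 0")
  for (iv in list(wbc_radius_um, rbc_radius_um))
    if (!num_ok(iv, 2) || iv[1] > iv[2] || iv[1] <= 0)
      stop("field_spec: radius intervals must be non-empty positive [lo, hi]")
  if (!num_ok(background_level) || background_level < 0) stop("field_spec: background_level must be >= 0")
  if (!num_ok(noise_sd) || noise_sd < 0) stop("field_spec: noise_sd must be >= 0")
  if (!num_ok(artifact_rate) || artifact_rate < 0) stop("field_spec: artifact_rate must be >= 0")
  if (!inherits(intensity_model, "intensity_model")) stop("field_spec: intensity_model must come from intensity_model()")
  spec <- structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um, depth_um = depth_um,
    wbc_conc = wbc_conc, rbc_conc = rbc_conc,
    wbc_radius_um = wbc_radius_um, rbc_radius_um = rbc_radius_um,
    intensity_model = intensity_model,
    background_level = background_level, noise_sd = noise_sd,
    artifact_rate = artifact_rate, overlap_allowed = isTRUE(overlap_allowed),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "field_spec")
  v <- field_volume_nl(spec)
  if (!is.finite(v) || v <= 0) stop("field_spec: imaged volume must be positive and finite")
  spec
}

#' Imaged volume of a field
#'
#' Volume in nanolitres of the fluid column imaged by one field:
#' `width_px * height_px * pixel_size_um^2 * depth_um * 1e-6`.
#'
#' @param spec a [field_spec()].
#' @return volume in nL.
#' @export
field_volume_nl <- function(spec) {
  spec$width_px * spec$height_px * spec$pixel_size_um^2 * spec$depth_um * 1e-6
}

# Derive a per-field RNG seed from a master seed and field index so parallel
# or out-of-order generation is reproducible. Kept below 2^31 - 1.
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483647 + 48271 * as.double(index)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. With seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
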
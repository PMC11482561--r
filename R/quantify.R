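#' Chip imaging specification
#'
#' @param volume_per_image_nl fluid volume imaged per field, nanolitres. The
#'   default is the chip imager's calibrated 23.8144 nL per image.
#' @param n_images number of fields imaged for one measurement. The default
#'   of 42 images about 1 uL (42 x 23.8144 nL = 1.0002 uL).
#' @return list of class `chip_spec`.
#' @export
chip_spec <- function(volume_per_image_nl = 23.8144, n_images = 42L) {
  if (volume_per_image_nl <= 0 || n_images < 1)
    stop("chip_spec: volume_per_image_nl and n_images must be positive")
  structure(list(volume_per_image_nl = volume_per_image_nl,
                 n_images = as.integer(n_images)), class = "chip_spec")
}

#' Staining / sample dilution specification
#'
#' The staining protocol brings a 40 uL CSF aliquot to an 84 uL stained
#' volume, a dilution factor of 84/40 = 2.1. An additional pre-dilution of
#' the sample itself is carried in `sample_dilution_factor`.
#'
#' @param stained_total_ul total volume after staining, uL.
#' @param sample_ul sample volume stained, uL.
#' @param sample_dilution_factor pre-dilution of the sample (>= 1).
#' @return list of class `dilution_spec`.
#' @export
dilution_spec <- function(stained_total_ul = 84, sample_ul = 40,
                          sample_dilution_factor = 1) {
  if (sample_ul <= 0) stop("dilution_spec: sample_ul must be > 0")
  if (stained_total_ul < sample_ul)
    stop("dilution_spec: stained_total_ul must be >= sample_ul")
  if (sample_dilution_factor < 1)
    stop("dilution_spec: sample_dilution_factor must be >= 1")
  structure(list(stained_total_ul = stained_total_ul, sample_ul = sample_ul,
                 sample_dilution_factor = sample_dilution_factor),
            class = "dilution_spec")
}

#' Bead standard specification for absolute counting
#'
#' @param bead_concentration bead concentration in the analyzed mixture,
#'   beads/uL.
#' @param sample_volume_ul volume of tested sample, uL.
#' @param dilution_factor sample dilution factor (>= 1).
#' @return list of class `bead_spec`.
#' @export
bead_spec <- function(bead_concentration, sample_volume_ul, dilution_factor = 1) {
  if (bead_concentration <= 0 || sample_volume_ul <= 0)
    stop("bead_spec: bead_concentration and sample_volume_ul must be > 0")
  if (dilution_factor < 1) stop("bead_spec: dilution_factor must be >= 1")
  structure(list(bead_concentration = bead_concentration,
                 sample_volume_ul = sample_volume_ul,
                 dilution_factor = dilution_factor), class = "bead_spec")
}

new_concentration_result <- function(value, modality, inputs) {
  structure(list(value = value, modality = modality, inputs = inputs),
            class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("<concentration_result> %s: %.2f cells x 10^6/L\n",
              x$modality, x$value))
  invisible(x)
}

#' Dilution factor due to the staining reagent
#'
#' `stained_total_ul / sample_ul`; 84/40 = 2.1 for the default protocol.
#'
#' @param dilution a [dilution_spec()].
#' @return scalar dilution factor.
#' @export
stain_dilution_factor <- function(dilution = dilution_spec()) {
  if (dilution$sample_ul <= 0) stop("stain_dilution_factor: zero sample volume")
  dilution$stained_total_ul / dilution$sample_ul
}

#' Concentration from chip imaging counts
#'
#' `value = total_count * 1000 / (volume_per_image_nl * n_images) *
#' sample_dilution_factor * stain_dilution_factor`, in cells x 10^6/L
#' (= cells/uL). The factor 1000 converts nanolitres to microlitres.
#'
#' @param total_count total cells counted over all images (>= 0).
#' @param chip a [chip_spec()].
#' @param dilution a [dilution_spec()].
#' @return a `concentration_result`.
#' @examples
#' microscanner_concentration(100, chip_spec(23.8144, 10))$value  # 881.82
#' @export
microscanner_concentration <- function(total_count, chip = chip_spec(),
                                       dilution = dilution_spec()) {
  if (total_count < 0) stop("microscanner_concentration: negative count")
  value <- total_count * 1000 / (chip$volume_per_image_nl * chip$n_images) *
    dilution$sample_dilution_factor * stain_dilution_factor(dilution)
  new_concentration_result(value, "microscanner",
                           list(total_count = total_count, chip = chip,
                                dilution = dilution))
}

#' Concentration from Neubauer chamber counts
#'
#' A single read is `cells_counted / (squares_counted * square_volume_ul)`.
#' When the chamber is read in duplicate (the usual protocol), pass the
#' per-read concentrations as `replicate_values` and the reported value is
#' their arithmetic mean. The standard large square holds 0.1 uL
#' (1 mm x 1 mm x 0.1 mm); counting five squares instead of four at low
#' counts is expressed through `squares_counted`.
#'
#' @param cells_counted cells counted over the read squares.
#' @param squares_counted number of large squares counted (>= 1).
#' @param square_volume_ul volume per large square, uL.
#' @param replicate_values optional per-read concentrations to average.
#' @return a `concentration_result`.
#' @export
neubauer_concentration <- function(cells_counted = NULL, squares_counted = 4L,
                                   square_volume_ul = 0.1,
                                   replicate_values = NULL) {
  if (squares_counted < 1) stop("neubauer_concentration: squares_counted must be >= 1")
  if (square_volume_ul <= 0) stop("neubauer_concentration: square_volume_ul must be > 0")
  if (!is.null(replicate_values)) {
    value <- mean(replicate_values)
  } else {
    if (is.null(cells_counted) || cells_counted < 0)
      stop("neubauer_concentration: cells_counted must be >= 0")
    value <- cells_counted / (squares_counted * square_volume_ul)
  }
  new_concentration_result(value, "neubauer",
                           list(cells_counted = cells_counted,
                                squares_counted = squares_counted,
                                square_volume_ul = square_volume_ul,
                                replicate_values = replicate_values))
}

#' Absolute count from a Trucount bead tube
#'
#' `value = (cells / beads) * (bead_concentration / sample_volume_ul) *
#' dilution_factor`. Note this follows the protocol's stated formula, which
#' divides the bead *concentration* by the tested sample volume; the
#' conventional kit formula instead uses beads-per-tube over acquired bead
#' events. The two coincide only when the bead concentration is given as
#' beads per tube.
#'
#' @param cells counted cells.
#' @param beads counted beads (>= 1; zero beads is an invalid measurement).
#' @param bead_spec a [bead_spec()].
#' @return a `concentration_result`.
#' @export
trucount_concentration <- function(cells, beads, bead_spec) {
  if (beads < 1) stop("trucount_concentration: zero beads counted - measurement invalid")
  if (cells < 0) stop("trucount_concentration: negative cell count")
  value <- (cells / beads) *
    (bead_spec$bead_concentration / bead_spec$sample_volume_ul) *
    bead_spec$dilution_factor
  new_concentration_result(value, "trucount",
                           list(cells = cells, beads = beads, bead_spec = bead_spec))
}

#' Absolute count from flow-count fluorospheres
#'
#' `value = (cells / beads) * bead_assay_concentration * dilution_factor`.
#'
#' @param cells counted cells.
#' @param beads counted beads (>= 1).
#' @param bead_assay_concentration bead assay concentration, beads/uL.
#' @param dilution_factor sample dilution factor.
#' @return a `concentration_result`.
#' @export
flowcount_concentration <- function(cells, beads, bead_assay_concentration,
                                    dilution_factor = 1) {
  if (beads < 1) stop("flowcount_concentration: zero beads counted - measurement invalid")
  if (cells < 0) stop("flowcount_concentration: negative cell count")
  value <- (cells / beads) * bead_assay_concentration * dilution_factor
  new_concentration_result(value, "flowcount",
                           list(cells = cells, beads = beads,
                                bead_assay_concentration = bead_assay_concentration,
                                dilution_factor = dilution_factor))
}
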
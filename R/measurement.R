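#' Measurement model for one counting modality
#'
#' Describes how a true cell concentration turns into one replicate
#' measurement for each of the three counting protocols:
#'
#' * `"neubauer"` — Poisson cells in the counted chamber volume
#'   (`squares_counted * square_volume_ul`), multiplied by a mean-one
#'   log-normal examiner error with coefficient of variation `examiner_cv`,
#'   then converted by hemocytometer arithmetic.
#' * `"flow"` — Poisson bead and cell event draws pushed through the
#'   fluorosphere absolute-count formula. The analyzed volume is implied by
#'   `bead_events_expected / bead_concentration`.
#' * `"microscanner"` — Poisson cells over `n_images` chip fields (at the
#'   staining/sample dilution), pushed through the chip concentration
#'   formula. `min_count` models the instrument's minimum reportable object
#'   count: runs with fewer detected objects report zero.
#'
#' `extra_cv` adds a mean-one log-normal instrument/handling error to any
#' modality (0 = pure counting statistics). All modalities are unbiased when
#' their multiplicative error is 0 (and asymptotically so with it, since the
#' log-normal terms have mean one).
#'
#' @param modality one of `"microscanner"`, `"neubauer"`, `"flow"`.
#' @param squares_counted,square_volume_ul,examiner_cv Neubauer parameters:
#'   number of large grid squares counted (4 by convention, 5 at low counts),
#'   volume per large square in uL (0.1 for the standard 1 mm x 1 mm x 0.1 mm
#'   geometry), examiner CV.
#' @param bead_concentration,bead_events_expected flow parameters: bead assay
#'   concentration (beads/uL) and expected bead events.
#' @param chip,dilution microscanner parameters ([chip_spec()],
#'   [dilution_spec()]).
#' @param min_count microscanner minimum reportable object count.
#' @param extra_cv extra multiplicative CV (all modalities).
#' @return list of class `measurement_model`.
#' @export
measurement_model <- function(modality = c("microscanner", "neubauer", "flow"),
                              squares_counted = 4L, square_volume_ul = 0.1,
                              examiner_cv = 0,
                              bead_concentration = 1000, bead_events_expected = 5000,
                              chip = chip_spec(), dilution = dilution_spec(),
                              min_count = 0L, extra_cv = 0) {
  modality <- match.arg(modality)
  if (squares_counted < 1) stop("measurement_model: squares_counted must be >= 1")
  if (square_volume_ul <= 0) stop("measurement_model: square_volume_ul must be > 0")
  if (examiner_cv < 0 || extra_cv < 0) stop("measurement_model: CVs must be >= 0")
  if (bead_concentration <= 0 || bead_events_expected <= 0)
    stop("measurement_model: bead parameters must be > 0")
  if (min_count < 0) stop("measurement_model: min_count must be >= 0")
  structure(list(modality = modality,
                 squares_counted = as.integer(squares_counted),
                 square_volume_ul = square_volume_ul, examiner_cv = examiner_cv,
                 bead_concentration = bead_concentration,
                 bead_events_expected = bead_events_expected,
                 chip = chip, dilution = dilution,
                 min_count = as.integer(min_count), extra_cv = extra_cv),
            class = "measurement_model")
}

# Mean-one multiplicative log-normal error with coefficient of variation cv.
lnorm_error <- function(cv) {
  if (cv <= 0) return(1)
  s <- sqrt(log(1 + cv^2))
  rlnorm(1, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate one replicate measurement of a sample
#'
#' Draws one (WBC, RBC) measurement of a sample with the given true
#' concentrations under a [measurement_model()]. Intermediate draws (counts,
#' bead events) are returned in `detail` so any reported value can be
#' recomputed by hand from the logged draw.
#'
#' @param true_wbc,true_rbc true concentrations, cells x 10^6/L.
#' @param model a [measurement_model()].
#' @param seed optional integer seed.
#' @return list `wbc`, `rbc` (measured concentrations), `valid` (FALSE when a
#'   flow draw counted zero beads), `detail` (logged intermediate draws).
#' @export
simulate_measurement <- function(true_wbc, true_rbc = 0, model, seed = NULL) {
  if (!inherits(model, "measurement_model")) stop("model must be a measurement_model")
  if (true_wbc < 0 || true_rbc < 0) stop("true concentrations must be >= 0")
  with_seed(seed, {
    switch(model$modality,
      neubauer = {
        vol <- model$squares_counted * model$square_volume_ul
        n_w <- rpois(1, true_wbc * vol); n_r <- rpois(1, true_rbc * vol)
        e_w <- lnorm_error(model$examiner_cv) * lnorm_error(model$extra_cv)
        e_r <- lnorm_error(model$examiner_cv) * lnorm_error(model$extra_cv)
        list(wbc = n_w * e_w / vol, rbc = n_r * e_r / vol, valid = TRUE,
             detail = list(wbc_count = n_w, rbc_count = n_r, counted_volume_ul = vol,
                           wbc_error = e_w, rbc_error = e_r))
      },
      flow = {
        vol <- model$bead_events_expected / model$bead_concentration
        beads <- rpois(1, model$bead_events_expected)
        n_w <- rpois(1, true_wbc * vol); n_r <- rpois(1, true_rbc * vol)
        if (beads == 0L) {
          return(list(wbc = NA_real_, rbc = NA_real_, valid = FALSE,
                      detail = list(beads = 0L, reason = "zero beads counted")))
        }
        e_w <- lnorm_error(model$extra_cv); e_r <- lnorm_error(model$extra_cv)
        f <- function(cells, e)
          flowcount_concentration(cells, beads, model$bead_concentration, 1)$value * e
        list(wbc = f(n_w, e_w), rbc = f(n_r, e_r), valid = TRUE,
             detail = list(wbc_count = n_w, rbc_count = n_r, beads = beads,
                           analyzed_volume_ul = vol))
      },
      microscanner = {
        dil <- stain_dilution_factor(model$dilution) * model$dilution$sample_dilution_factor
        vol_ul <- model$chip$volume_per_image_nl * model$chip$n_images / 1000
        lam <- function(conc) conc / dil * vol_ul
        n_w <- rpois(1, lam(true_wbc)); n_r <- rpois(1, lam(true_rbc))
        rep_w <- if (n_w < model$min_count) 0L else n_w
        rep_r <- if (n_r < model$min_count) 0L else n_r
        e_w <- lnorm_error(model$extra_cv); e_r <- lnorm_error(model$extra_cv)
        f <- function(n, e) microscanner_concentration(n, model$chip, model$dilution)$value * e
        list(wbc = f(rep_w, e_w), rbc = f(rep_r, e_r), valid = TRUE,
             detail = list(wbc_count = n_w, rbc_count = n_r,
                           wbc_reported = rep_w, rbc_reported = rep_r,
                           imaged_volume_ul = vol_ul, dilution = dil))
      })
  })
}

#' Simulate a replicate series at one concentration level
#'
#' Convenience wrapper drawing `n` replicate measurements (per-replicate
#' seeds derived from `seed`) and returning the measured values for one
#' class.
#'
#' @param true_conc true concentration, cells x 10^6/L.
#' @param model a [measurement_model()].
#' @param n number of replicates.
#' @param seed master seed.
#' @param class `"wbc"` or `"rbc"` (the simulated sample contains this class
#'   only).
#' @return numeric vector of length `n` (invalid draws are `NA`).
#' @export
simulate_replicates <- function(true_conc, model, n = 20L, seed = 1L,
                                class = c("wbc", "rbc")) {
  class <- match.arg(class)
  vapply(seq_len(n), function(i) {
    m <- if (class == "wbc")
      simulate_measurement(true_conc, 0, model, seed = derive_seed(seed, i))
    else
      simulate_measurement(0, true_conc, model, seed = derive_seed(seed, i))
    m[[class]]
  }, numeric(1))
}
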
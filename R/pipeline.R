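#' Run configuration for the counting pipeline
#'
#' Bundles every tunable of the detect / gate / quantify chain plus the
#' statistical conventions, and round-trips to a human-readable JSON file.
#' Unknown keys in a config file are rejected.
#'
#' @param detector a [detector_config()].
#' @param thresholds a [gate_thresholds()].
#' @param c4 a [c4_rules()].
#' @param chip a [chip_spec()]; `n_images` is overridden by the actual number
#'   of fields when counting.
#' @param dilution a [dilution_spec()].
#' @param radius_range_um size gate applied after detection, micrometres.
#' @param lob_percentile percentile used by [limit_of_blank()].
#' @param ba_ci_method `"t"` or `"z"` bias CI for [bland_altman()].
#' @param seed integer seed for any simulation step.
#' @param verbosity 0 silent, 1 progress messages to stderr.
#' @return list of class `run_config`.
#' @export
run_config <- function(detector = detector_config(),
                       thresholds = gate_thresholds(),
                       c4 = c4_rules(),
                       chip = chip_spec(),
                       dilution = dilution_spec(),
                       radius_range_um = c(2, 7),
                       lob_percentile = 95,
                       ba_ci_method = "t",
                       seed = 1L, verbosity = 1L) {
  structure(list(detector = detector, thresholds = thresholds, c4 = c4,
                 chip = chip, dilution = dilution,
                 radius_range_um = radius_range_um,
                 lob_percentile = lob_percentile, ba_ci_method = ba_ci_method,
                 seed = as.integer(seed), verbosity = as.integer(verbosity)),
            class = "run_config")
}

run_config_classes <- c(detector = "detector_config", thresholds = "gate_thresholds",
                        c4 = "c4_rules", chip = "chip_spec", dilution = "dilution_spec")

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- run_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("read_run_config: unknown config keys: ", paste(unknown, collapse = ", "))
  for (nm in names(raw)) {
    val <- raw[[nm]]
    if (nm %in% names(run_config_classes)) {
      sub_unknown <- setdiff(names(val), names(base[[nm]]))
      if (length(sub_unknown))
        stop("read_run_config: unknown keys under '", nm, "': ",
             paste(sub_unknown, collapse = ", "))
      merged <- utils::modifyList(unclass(base[[nm]]), val)
      base[[nm]] <- structure(merged, class = run_config_classes[[nm]])
    } else base[[nm]] <- val
  }
  base
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

log_msg <- function(config, ...) {
  if (isTRUE(config$verbosity >= 1)) message(...)
}

#' Count cells in a set of in-memory fields
#'
#' The core counting chain: per field, detect circles on the summed
#' fluorescence raster, apply the size gate, measure intensities, gate
#' events, and accumulate the adjusted class counts; then convert totals to
#' sample concentrations with the chip formula (the number of fields sets
#' `n_images`).
#'
#' @param fields list of [field_image()]s.
#' @param config a [run_config()].
#' @return list of class `count_report`: `wbc`, `rbc`
#'   (`concentration_result`s), `per_field` (data.frame of per-field
#'   counts), `total_wbc`, `total_rbc`, `total_artifacts`, `n_fields`.
#' @export
count_fields <- function(fields, config = run_config()) {
  n <- length(fields)
  if (n == 0) stop("count_fields: no fields")
  per <- data.frame(field = seq_len(n), events = 0L, wbc = 0L, rbc = 0L,
                    artifacts = 0L, doublets = 0L)
  for (k in seq_len(n)) {
    f <- fields[[k]]
    det <- detect_field(f, config$detector, config$radius_range_um)
    g <- gate_events(det, config$thresholds, config$c4)
    per$events[k] <- nrow(det)
    per$wbc[k] <- g$adjusted_wbc
    per$rbc[k] <- g$adjusted_rbc
    per$artifacts[k] <- g$artifact_count
    per$doublets[k] <- g$doublet_count
    log_msg(config, sprintf("field %d/%d: %d events, WBC %d, RBC %d",
                            k, n, per$events[k], per$wbc[k], per$rbc[k]))
  }
  chip <- config$chip
  chip$n_images <- n
  structure(list(
    wbc = microscanner_concentration(sum(per$wbc), chip, config$dilution),
    rbc = microscanner_concentration(sum(per$rbc), chip, config$dilution),
    per_field = per,
    total_wbc = sum(per$wbc), total_rbc = sum(per$rbc),
    total_artifacts = sum(per$artifacts), n_fields = n
  ), class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf("<count_report> %d fields: WBC %.2f, RBC %.2f cells x 10^6/L (%d/%d cells, %d artifacts)\n",
              x$n_fields, x$wbc$value, x$rbc$value,
              x$total_wbc, x$total_rbc, x$total_artifacts))
  invisible(x)
}

#' Count a sample from field images on disk
#'
#' Reads each field (multi-page TIFF written by [write_field()], or three
#' PNGs), runs [count_fields()], and optionally persists per-field CSV and a
#' JSON report. Unreadable files are reported per file and skipped; the
#' report's `status` is nonzero when any file failed.
#'
#' @param image_paths character vector of field image paths.
#' @param config a [run_config()].
#' @param out_dir optional output directory for `per_field.csv`,
#'   `detections.csv` and `report.json`.
#' @return a `count_report` with extra elements `errors` (named list of
#'   per-file failures) and `status`.
#' @export
run_count <- function(image_paths, config = run_config(), out_dir = NULL) {
  fields <- list(); errors <- list()
  for (p in image_paths) {
    f <- tryCatch(read_field(p), error = function(e) e)
    if (inherits(f, "error")) {
      errors[[p]] <- conditionMessage(f)
      log_msg(config, "run_count: skipping ", p, ": ", conditionMessage(f))
    } else fields[[length(fields) + 1L]] <- f
  }
  if (length(fields) == 0) stop("run_count: no readable fields")
  rep <- count_fields(fields, config)
  rep$errors <- errors
  rep$status <- if (length(errors)) 1L else 0L
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(rep$per_field, file.path(out_dir, "per_field.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(wbc = rep$wbc$value, rbc = rep$rbc$value,
           total_wbc = rep$total_wbc, total_rbc = rep$total_rbc,
           total_artifacts = rep$total_artifacts,
           n_fields = rep$n_fields, status = rep$status,
           errors = errors),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  rep
}

read_replicate_csv <- function(csv_path) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("level_label", "expected", "replicate_index", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("validation CSV is missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Run the analytical validation suite on a replicate CSV
#'
#' The CSV needs columns `level_label`, `expected`, `replicate_index`,
#' `value`. Produces linearity (on per-level means; needs >= 3 levels),
#' a precision profile, and - when blank (`expected == 0`) rows are present -
#' the limit of blank and limit of detection.
#'
#' @param csv_path path to the replicate table.
#' @param config a [run_config()] (supplies the LOB percentile).
#' @param out_dir optional output directory for `validation.json`.
#' @return list of class `validation_report`: `linearity`, `precision`,
#'   `loblod` (or `NULL`).
#' @export
run_validate <- function(csv_path, config = run_config(), out_dir = NULL) {
  df <- read_replicate_csv(csv_path)
  split_levels <- split(df, df$level_label)
  sets <- lapply(split_levels, function(d)
    replicate_set(d$level_label[1], d$expected[1], d$value))
  ord <- order(vapply(sets, `[[`, numeric(1), "expected"))
  sets <- sets[ord]
  lin <- linearity(sets)
  prec <- precision_profile(sets)
  blanks <- df$value[df$expected == 0]
  loblod <- NULL
  if (length(blanks) > 0) {
    lob <- limit_of_blank(blanks, config$lob_percentile)
    nonblank <- Filter(function(s) s$expected > 0, sets)
    if (length(nonblank)) loblod <- limit_of_detection(nonblank, lob)
  }
  rep <- structure(list(linearity = lin, precision = prec, loblod = loblod),
                   class = "validation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- list(r = lin$r, r_squared = lin$r_squared,
                levels = prec$table,
                lob = if (is.null(loblod)) NULL else loblod$lob,
                lod = if (is.null(loblod)) NULL else loblod$lod)
    jsonlite::write_json(out, file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' Run the method-comparison suite on a paired CSV
#'
#' The CSV needs numeric columns `x` (comparator method) and `y` (test
#' method). Computes Pearson correlation, Passing-Bablok regression and
#' Bland-Altman analysis, optionally restricted to a subrange first.
#'
#' @param csv_path path to the paired table.
#' @param config a [run_config()] (supplies the Bland-Altman CI method).
#' @param range optional `c(lo, hi)` subrange (on the comparator values).
#' @param out_dir optional output directory for `comparison.json`.
#' @return list of class `comparison_report`: `pearson`, `passing_bablok`,
#'   `bland_altman`, `n`.
#' @export
run_compare <- function(csv_path, config = run_config(), range = NULL,
                        out_dir = NULL) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  missing <- setdiff(c("x", "y"), names(df))
  if (length(missing))
    stop("comparison CSV is missing column(s): ", paste(missing, collapse = ", "))
  pairs <- paired_measurements(df$x, df$y)
  if (!is.null(range)) pairs <- subrange(pairs, range[1], range[2])
  pr <- pearson_correlation(pairs)
  pb <- passing_bablok(pairs)
  ba <- bland_altman(pairs, ci_method = config$ba_ci_method)
  rep <- structure(list(pearson = pr, passing_bablok = pb, bland_altman = ba,
                        n = pairs$n), class = "comparison_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(n = pairs$n, r = pr$r, r_squared = pr$r_squared,
           slope = pb$slope, slope_ci = pb$slope_ci,
           intercept = pb$intercept, intercept_ci = pb$intercept_ci,
           mean_bias = ba$mean_bias, bias_ci = ba$bias_ci,
           loa = c(ba$loa_low, ba$loa_high)),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  }
  rep
}
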
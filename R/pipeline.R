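#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end prediction workflow with
#' the production defaults: instrument conditions 443.15 K and
#' 2.2e-8 atm, keep the 1000 lowest-energy conformers per isomer,
#' 40 kJ/mol energy window after the semi-empirical stage, 20 kJ/mol
#' for the DFT set, duplicate removal at 0.03 kJ/mol energy agreement
#' with align score > 0.98, and all four energy variants.
#'
#' @param peptide Peptide sequence.
#' @param series Protonation series: `"nitrogen"`, `"oxygen"`, `"both"`.
#' @param temperature Kelvin.
#' @param pressure atm.
#' @param keep_n Conformers kept per isomer.
#' @param window_semiempirical,window_dft Energy windows, kJ/mol.
#' @param dedup_energy_tol,dedup_score_threshold Duplicate-removal
#'   thresholds (kJ/mol; align score).
#' @param variants Energy variants to run.
#' @param annotation_tolerance Peak-matching half window, Da/charge.
#' @param ensemble_path,measured_path,out_dir Optional paths.
#' @param seed Integer seed (only synthetic fixtures consume it; the
#'   pipeline itself is deterministic).
#' @param allow_nonbasic Permit a non-K/R C-terminus.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(peptide = "GAVLK", series = "nitrogen",
                            temperature = 443.15, pressure = 2.2e-8,
                            keep_n = 1000L, window_semiempirical = 40,
                            window_dft = 20, dedup_energy_tol = 0.03,
                            dedup_score_threshold = 0.98,
                            variants = c("E", "EHC", "GE", "GEEC"),
                            annotation_tolerance = 0.5,
                            ensemble_path = NULL, measured_path = NULL,
                            out_dir = NULL, seed = 1L,
                            allow_nonbasic = FALSE) {
  stopifnot(temperature > 0, pressure > 0, keep_n >= 1,
            window_semiempirical > 0, window_dft > 0,
            dedup_energy_tol > 0, dedup_score_threshold > 0,
            annotation_tolerance > 0)
  variants <- match.arg(variants, .variants, several.ok = TRUE)
  structure(list(
    peptide = parse_sequence(peptide), series = series,
    temperature = temperature, pressure = pressure,
    keep_n = as.integer(keep_n),
    window_semiempirical = window_semiempirical,
    window_dft = window_dft,
    dedup_energy_tol = dedup_energy_tol,
    dedup_score_threshold = dedup_score_threshold,
    variants = variants,
    annotation_tolerance = annotation_tolerance,
    ensemble_path = ensemble_path, measured_path = measured_path,
    out_dir = out_dir, seed = as.integer(seed),
    allow_nonbasic = allow_nonbasic
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the [pipeline_config()] argument names;
#' `...` overrides file values.
#'
#' @param path YAML file.
#' @param ... Overrides, as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

pipeline_log <- function(..., quiet = FALSE) {
  if (!quiet) message(...)
}

#' Run the end-to-end intensity prediction
#'
#' Executes the full stage list on a conformer ensemble: keep-N pruning
#' per isomer, energy-window filtering (20 kJ/mol for DFT-stage
#' ensembles, 40 kJ/mol otherwise), duplicate removal, thermochemical
#' corrections (when a corrected variant is requested), one global
#' Boltzmann distribution per energy variant, and the mapping to
#' relative y/b-ion intensities. Conformer counts surviving each stage
#' are logged and returned.
#'
#' @param config A [pipeline_config()].
#' @param ensemble Ensemble tibble; defaults to reading
#'   `config$ensemble_path`.
#' @param quiet Suppress progress messages.
#' @return A list of class `prediction_bundle`: `config`,
#'   `stage_counts`, `ensemble` (post-filtering), `thermo`,
#'   `populations`, `intensities` (both with a `variant` column). When
#'   `config$out_dir` is set, per-stage CSV reports and a run log are
#'   written there.
#' @export
run_predict <- function(config, ensemble = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(ensemble)) {
    if (is.null(config$ensemble_path)) {
      stop("no ensemble given and no ensemble_path configured",
           call. = FALSE)
    }
    ensemble <- read_ensemble(config$ensemble_path)
  }
  ensemble <- validate_ensemble(ensemble)
  if (nrow(ensemble) == 0L) stop("stage read: empty ensemble",
                                 call. = FALSE)
  isomers <- enumerate_protonation_isomers(config$peptide, config$series,
                                           config$allow_nonbasic)
  counts <- c(read = nrow(ensemble))
  pipeline_log("read: ", nrow(ensemble), " conformers, ",
               dplyr::n_distinct(ensemble$isomer_label), " isomers",
               quiet = quiet)

  ens <- keep_lowest(ensemble, config$keep_n)
  counts["keep_lowest"] <- nrow(ens)
  window <- if (all(ens$stage == "dft")) config$window_dft else
    config$window_semiempirical
  ens <- filter_energy_window(ens, window)
  counts["energy_window"] <- nrow(ens)
  ens <- deduplicate(ens, config$dedup_energy_tol,
                     config$dedup_score_threshold)
  counts["deduplicate"] <- nrow(ens)
  pipeline_log("keep_lowest(", config$keep_n, ") -> ",
               counts["keep_lowest"], "; window(", window, " kJ/mol) -> ",
               counts["energy_window"], "; deduplicate -> ",
               counts["deduplicate"], quiet = quiet)

  needs_thermo <- any(config$variants != "E")
  thermo <- NULL
  if (needs_thermo) {
    cond <- thermo_conditions(config$temperature, config$pressure)
    thermo <- thermo_corrections(ens, cond)
  }
  populations <- purrr::map(config$variants, function(v) {
    aggregate_populations(ens, thermo = thermo, variant = v,
                          temperature = config$temperature,
                          isomers = isomers$label) |>
      dplyr::mutate(variant = v, .before = 1)
  }) |> dplyr::bind_rows()
  intensities <- purrr::map(config$variants, function(v) {
    predict_intensities(populations[populations$variant == v, ],
                        config$peptide) |>
      dplyr::mutate(variant = v, .before = 1)
  }) |> dplyr::bind_rows()

  bundle <- structure(list(
    config = config,
    stage_counts = tibble::tibble(stage = names(counts),
                                  n_conformers = unname(counts)),
    ensemble = ens, thermo = thermo,
    populations = populations, intensities = intensities
  ), class = "prediction_bundle")

  if (!is.null(config$out_dir)) write_prediction_reports(bundle, quiet)
  bundle
}

write_prediction_reports <- function(bundle, quiet = FALSE) {
  dir.create(bundle$config$out_dir, showWarnings = FALSE,
             recursive = TRUE)
  out <- function(name) file.path(bundle$config$out_dir, name)
  utils::write.csv(bundle$stage_counts, out("stage_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$populations, out("populations.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$intensities, out("intensities.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$thermo)) {
    utils::write.csv(bundle$thermo, out("thermochemistry.csv"),
                     row.names = FALSE)
  }
  cfg <- bundle$config
  log_lines <- c(
    sprintf("peptide: %s", cfg$peptide),
    sprintf("series: %s", cfg$series),
    sprintf("temperature: %g K", cfg$temperature),
    sprintf("pressure: %g atm", cfg$pressure),
    sprintf("keep_n: %d conformers per isomer", cfg$keep_n),
    sprintf("windows: %g kJ/mol (semi-empirical), %g kJ/mol (DFT)",
            cfg$window_semiempirical, cfg$window_dft),
    sprintf("dedup: |dE| <= %g kJ/mol and align score > %g",
            cfg$dedup_energy_tol, cfg$dedup_score_threshold),
    sprintf("variants: %s", paste(cfg$variants, collapse = ", ")),
    sprintf("stage counts: %s",
            paste(bundle$stage_counts$stage,
                  bundle$stage_counts$n_conformers,
                  sep = "=", collapse = ", "))
  )
  writeLines(log_lines, out("run_log.txt"))
  pipeline_log("reports written to ", cfg$out_dir, quiet = quiet)
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat("Intensity prediction for", x$config$peptide, "(",
      paste(x$config$variants, collapse = ", "), ")\n")
  cat("Stage counts:",
      paste(x$stage_counts$stage, x$stage_counts$n_conformers,
            sep = "=", collapse = ", "), "\n")
  y <- x$intensities[x$intensities$series == "y", ]
  for (v in unique(y$variant)) {
    yy <- y[y$variant == v, ]
    cat(sprintf("  %-4s %s\n", v,
                paste(sprintf("%s=%.4f", yy$ion, yy$rel_intensity),
                      collapse = " ")))
  }
  invisible(x)
}

#' Score predictions against a measured spectrum
#'
#' Annotates the measured peak list with the peptide's theoretical
#' ions, normalises to the strongest detected y ion, and reports the
#' log relative errors, order agreement, and random-match baseline
#' probabilities for the compared y ions.
#'
#' @param config A [pipeline_config()].
#' @param predicted [predict_intensities()] output (or the
#'   `intensities` table of one variant from [run_predict()]).
#' @param measured Peak-list tibble or path readable by [read_peaks()];
#'   defaults to `config$measured_path`.
#' @param quiet Suppress progress messages.
#' @return A list of class `comparison_bundle`: `annotated`,
#'   `measured_intensities`, `report` (a `comparison_report` over the
#'   shared y ions), `baseline`. CSV reports are written to
#'   `config$out_dir` when set.
#' @export
run_compare <- function(config, predicted, measured = NULL,
                        quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(measured)) measured <- config$measured_path
  if (is.character(measured)) measured <- read_peaks(measured)
  ions <- ion_table(config$peptide)
  annotated <- annotate_peaks(measured, ions,
                              tolerance = config$annotation_tolerance)
  meas_rel <- relative_intensities(annotated)
  pred_y <- predicted[predicted$series == "y", ]
  meas_y <- meas_rel[meas_rel$series == "y", ]
  report <- log_error(pred_y, meas_y)
  baseline <- random_match_baseline(max(report$n_ions, 2L))
  pipeline_log(sprintf(
    "compared %d y ions: sum |logErr| = %.4f, order match = %s",
    report$n_ions, report$sum_abs_log_err, report$order_match),
    quiet = quiet)
  bundle <- structure(list(annotated = annotated,
                           measured_intensities = meas_rel,
                           report = report, baseline = baseline),
                      class = "comparison_bundle")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tidy(report),
                     file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  bundle
}

#' @export
print.comparison_bundle <- function(x, ...) {
  print(x$report)
  cat(sprintf(
    "  random-match baseline: order %.3g, intensities %.3g\n",
    x$baseline$order_probability, x$baseline$intensity_probability))
  invisible(x)
}
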
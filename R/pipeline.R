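# Orchestration: an in-memory end-to-end study runner for synthetic cohorts,
# and file-based commands (simulate / fit / train / measure / evaluate)
# mirroring how the pipeline is driven from the shell over NIfTI + CSV + JSON
# artifacts. A thin command-line wrapper lives in inst/cli/rsi3c.R.

#' Default run configuration
#'
#' Collects the tunable constants of the analysis with their standard values:
#' classification threshold 0.5 on the probability map, 10 mm (1 cm) ROI
#' expansion, 26-connectivity, lookup binning/prior/smoothing, specificity
#' floor 0.90 for the constrained operating point, and alpha 0.025 (two
#' primary outcomes).
#'
#' @param threshold Probability threshold for voxel classification.
#' @param expand_mm ROI expansion in mm.
#' @param connectivity 6, 18 or 26.
#' @param bins,prior_cancer,smoothing_sigma_bins,pseudocount Lookup-table
#'   settings, see [build_lookup()].
#' @param nonneg Non-negativity constraint on the component fit.
#' @param min_specificity Specificity floor for the constrained operating
#'   point.
#' @param alpha Significance level for the paired tests.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(threshold = 0.5, expand_mm = 10.0, connectivity = 26,
                       bins = 128L, prior_cancer = 0.5,
                       smoothing_sigma_bins = 1, pseudocount = 0.5,
                       nonneg = TRUE, min_specificity = 0.90, alpha = 0.025) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

fit_patient_timepoint <- function(dwi, control_roi, fixed_adcs, config) {
  maps <- fit_components(dwi, fixed_adcs, nonneg = config$nonneg)
  gm <- geometric_mean_map(maps)
  factor <- normalization_factor(gm, control_roi)
  normalize_components(maps, factor)
}

#' Run a full synthetic study in memory
#'
#' Executes the entire pipeline on a [generate_cohort()] phantom: per patient
#' and timepoint the DWI is simulated, the three-component model fitted and
#' normalized to the control ROI, the classifier trained on the pooled
#' pre-treatment cancer/control voxels of all patients, each timepoint
#' measured automatically, and the mean ADC extracted — yielding the cohort
#' table the statistics layer consumes.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param config A [run_config()].
#' @return List with `dataset` (a [cohort_dataset()]), `lookup` (the trained
#'   `posterior_lookup`) and `truth` (the cohort's true diameters).
#' @export
run_phantom_study <- function(cohort, config = run_config()) {
  fitted <- list()
  cancer_pairs <- list()
  control_pairs <- list()
  for (id in names(cohort$configs)) {
    cfg <- cohort$configs[[id]]
    pat <- generate_patient(cfg)
    per_tp <- list()
    for (tp in TIMEPOINTS) {
      maps <- fit_patient_timepoint(pat$timepoints[[tp]], pat$control_roi,
                                    cfg$fixed_adcs, config)
      adc <- compute_adc_map(pat$timepoints[[tp]])
      per_tp[[tp]] <- list(c1 = maps$c1, c2 = maps$c2,
                           mean_adc = mean_adc(adc, pat$cancer_roi))
      if (tp == "pre") {
        cancer_pairs[[id]] <- cbind(maps$c1[pat$cancer_roi$mask],
                                    maps$c2[pat$cancer_roi$mask])
        control_pairs[[id]] <- cbind(maps$c1[pat$control_roi$mask],
                                     maps$c2[pat$control_roi$mask])
      }
    }
    fitted[[id]] <- list(timepoints = per_tp, cancer_roi = pat$cancer_roi,
                         grid = cfg$grid)
  }
  lookup <- build_lookup(do.call(rbind, cancer_pairs),
                         do.call(rbind, control_pairs),
                         bins = config$bins,
                         prior_cancer = config$prior_cancer,
                         smoothing_sigma_bins = config$smoothing_sigma_bins,
                         pseudocount = config$pseudocount)
  rows <- list()
  for (id in names(fitted)) {
    f <- fitted[[id]]
    for (tp in TIMEPOINTS) {
      m <- f$timepoints[[tp]]
      prob <- posterior_map(component_maps(m$c1, m$c2, m$c1 * 0,
                                           cohort$configs[[id]]$fixed_adcs,
                                           f$grid, normalization_factor = 1),
                            lookup)
      meas <- measure_timepoint(prob, f$cancer_roi,
                                threshold = config$threshold,
                                expand_mm = config$expand_mm,
                                connectivity = config$connectivity)
      dce <- cohort$dce$dce_diameter_cm[cohort$dce$patient_id == id &
                                          cohort$dce$timepoint == tp]
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = id, timepoint = tp,
        rsi_diameter_cm = meas$diameter_cm,
        dce_diameter_cm = dce, mean_adc = m$mean_adc,
        rsi_n_voxels = meas$n_voxels)
    }
  }
  records <- do.call(rbind, rows)
  list(dataset = cohort_dataset(records, cohort$labels), lookup = lookup,
       truth = cohort$true_diameters_cm)
}

# ---------------------------------------------------------------------------
# File-based commands

study_paths <- function(dir, patient, timepoint) {
  base <- file.path(dir, patient, timepoint)
  list(dir = base,
       dwi = file.path(base, "dwi.nii.gz"),
       bval = file.path(base, "dwi.bval"),
       cancer = file.path(dir, patient, "cancer_pre.nii.gz"),
       control = file.path(dir, patient, "control.nii.gz"),
       derived = file.path(dir, patient, timepoint, "derived"))
}

#' Write a synthetic study to disk
#'
#' Lays out a [generate_cohort()] phantom in the directory structure the
#' file-based commands consume: per patient and timepoint a `dwi.nii.gz` +
#' `dwi.bval` pair, per patient the pre-treatment cancer and control masks,
#' plus `cohort.csv` (DCE diameters and pCR labels; RSI and ADC columns
#' blank until measured) and `truth.json`.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
cmd_simulate <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$configs)) {
    cfg <- cohort$configs[[id]]
    pat <- generate_patient(cfg)
    for (tp in TIMEPOINTS) {
      p <- study_paths(dir, id, tp)
      dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
      write_volume(pat$timepoints[[tp]]$signal, cfg$grid, p$dwi)
      write_bvalues(cfg$bvalues, p$bval)
    }
    p <- study_paths(dir, id, "pre")
    write_volume(pat$cancer_roi$mask, cfg$grid, p$cancer)
    write_volume(pat$control_roi$mask, cfg$grid, p$control)
  }
  dce <- cohort$dce
  dce$rsi_diameter_cm <- NA_real_
  dce$mean_adc <- NA_real_
  dce <- merge(dce, cohort$labels, by = "patient_id")
  utils::write.csv(dce[order(dce$patient_id,
                             match(dce$timepoint, TIMEPOINTS)), ],
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = cohort$seed,
                            true_diameters_cm = cohort$true_diameters_cm,
                            labels = cohort$labels),
                       file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Fit and normalize one patient-timepoint from disk
#'
#' Reads the DWI series and the patient's control mask, fits the
#' three-component model, normalizes to the control ROI, and writes
#' `c1/c2/c3.nii.gz` plus a `fit_report.json` (normalization factor and a
#' residual summary) under the timepoint's `derived/` directory.
#'
#' @param dir Study directory (layout of [cmd_simulate()]).
#' @param patient,timepoint Which study to fit.
#' @param fixed_adcs An [rsi_fixed_adcs()].
#' @param config A [run_config()].
#' @return The derived directory, invisibly.
#' @export
cmd_fit <- function(dir, patient, timepoint, fixed_adcs,
                    config = run_config()) {
  p <- study_paths(dir, patient, timepoint)
  if (!file.exists(p$control))
    stop("missing control mask: ", p$control)
  dwi <- read_dwi(p$dwi, p$bval)
  control <- read_mask(p$control, "control")
  maps <- fit_components(dwi, fixed_adcs, nonneg = config$nonneg)
  gm <- geometric_mean_map(maps)
  factor <- normalization_factor(gm, control)
  maps <- normalize_components(maps, factor)
  dir.create(p$derived, recursive = TRUE, showWarnings = FALSE)
  write_volume(maps$c1, maps$grid, file.path(p$derived, "c1.nii.gz"))
  write_volume(maps$c2, maps$grid, file.path(p$derived, "c2.nii.gz"))
  write_volume(maps$c3, maps$grid, file.path(p$derived, "c3.nii.gz"))
  A <- rsi_design_matrix(dwi$bvalues, fixed_adcs)
  pred <- A %*% rbind(as.vector(maps$c1), as.vector(maps$c2),
                      as.vector(maps$c3)) * factor
  resid <- t(pred) - matrix(dwi$signal, ncol = length(dwi$bvalues))
  jsonlite::write_json(
    list(patient = patient, timepoint = timepoint,
         normalization_factor = factor,
         fixed_adcs = unclass(fixed_adcs),
         rms_residual = sqrt(mean(resid^2)),
         max_abs_residual = max(abs(resid))),
    file.path(p$derived, "fit_report.json"), digits = NA, auto_unbox = TRUE)
  invisible(p$derived)
}

#' Train the pooled classifier from fitted studies on disk
#'
#' Pools normalized pre-treatment (C1, C2) pairs from every listed patient's
#' cancer and control ROIs and writes the lookup table to JSON.
#'
#' @param dir Study directory.
#' @param patients Character vector of patient ids (all must have a fitted
#'   `pre` timepoint).
#' @param out_path Output JSON path.
#' @param config A [run_config()].
#' @return The trained `posterior_lookup`, invisibly.
#' @export
cmd_train_classifier <- function(dir, patients, out_path,
                                 config = run_config()) {
  if (length(patients) == 0) stop("no training studies given")
  cancer_pairs <- list()
  control_pairs <- list()
  for (id in patients) {
    p <- study_paths(dir, id, "pre")
    c1 <- read_volume(file.path(p$derived, "c1.nii.gz"))$volume
    c2 <- read_volume(file.path(p$derived, "c2.nii.gz"))$volume
    cancer <- read_mask(p$cancer, "cancer")
    control <- read_mask(p$control, "control")
    cancer_pairs[[id]] <- cbind(c1[cancer$mask], c2[cancer$mask])
    control_pairs[[id]] <- cbind(c1[control$mask], c2[control$mask])
  }
  lookup <- build_lookup(do.call(rbind, cancer_pairs),
                         do.call(rbind, control_pairs),
                         bins = config$bins,
                         prior_cancer = config$prior_cancer,
                         smoothing_sigma_bins = config$smoothing_sigma_bins,
                         pseudocount = config$pseudocount)
  save_lookup(lookup, out_path)
  invisible(lookup)
}

upsert_row <- function(df, row, keys) {
  match_mask <- rep(TRUE, nrow(df))
  for (k in keys) match_mask <- match_mask & df[[k]] == row[[k]]
  if (any(match_mask)) {
    for (col in names(row)) if (col %in% names(df))
      df[match_mask, col] <- row[[col]]
    df
  } else {
    for (col in setdiff(names(df), names(row))) row[[col]] <- NA
    rbind(df, row[names(df)])
  }
}

#' Measure one patient-timepoint and update the cohort CSV
#'
#' Loads the trained lookup and the fitted maps, computes the posterior map,
#' runs the automatic measurement against the patient's pre-treatment cancer
#' ROI, computes the mean ADC inside the same ROI, and upserts the
#' `(patient, timepoint)` row of the cohort CSV (re-running replaces rather
#' than duplicates the row).
#'
#' @param dir Study directory.
#' @param patient,timepoint Which study to measure.
#' @param lookup_path JSON lookup from [cmd_train_classifier()].
#' @param cohort_csv Cohort CSV path (created by [cmd_simulate()] or by
#'   hand).
#' @param config A [run_config()].
#' @return The [measure_timepoint()] result, invisibly.
#' @export
cmd_measure <- function(dir, patient, timepoint, lookup_path, cohort_csv,
                        config = run_config()) {
  if (!file.exists(lookup_path)) stop("missing lookup table: ", lookup_path)
  lookup <- load_lookup(lookup_path)
  p <- study_paths(dir, patient, timepoint)
  c1 <- read_volume(file.path(p$derived, "c1.nii.gz"))
  c2 <- read_volume(file.path(p$derived, "c2.nii.gz"))$volume
  cancer <- read_mask(p$cancer, "cancer")
  stop_if_grid_mismatch(c1$grid, cancer$grid, "maps and cancer ROI")
  prob <- structure(list(prob = array(
    lookup$posterior[cbind(bin_index(as.vector(c1$volume), lookup$c1_edges),
                           bin_index(as.vector(c2), lookup$c2_edges))],
    dim = c1$grid$shape), grid = c1$grid), class = "probability_map")
  meas <- measure_timepoint(prob, cancer, threshold = config$threshold,
                            expand_mm = config$expand_mm,
                            connectivity = config$connectivity)
  dwi <- read_dwi(p$dwi, p$bval)
  madc <- mean_adc(compute_adc_map(dwi), cancer)
  df <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  df <- upsert_row(df, data.frame(patient_id = patient,
                                  timepoint = timepoint,
                                  rsi_diameter_cm = meas$diameter_cm,
                                  mean_adc = madc),
                   c("patient_id", "timepoint"))
  utils::write.csv(df, cohort_csv, row.names = FALSE)
  invisible(meas)
}

#' Evaluate a cohort CSV and write result artifacts
#'
#' Runs [evaluate_cohort()] on the CSV and writes `results.json` plus a flat
#' `results_table.csv` to the output directory.
#'
#' @param cohort_csv Cohort CSV with measurements and `pcr` labels.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return The `cohort_evaluation`, invisibly.
#' @export
cmd_evaluate <- function(cohort_csv, out_dir, config = run_config()) {
  dataset <- read_cohort_csv(cohort_csv)
  ev <- evaluate_cohort(dataset, alpha = config$alpha,
                        min_specificity = config$min_specificity)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(strip_classes(ev), file.path(out_dir, "results.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  utils::write.csv(evaluation_table(ev),
                   file.path(out_dir, "results_table.csv"), row.names = FALSE)
  invisible(ev)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}
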
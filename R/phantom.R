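# Synthetic longitudinal DWI phantom: a two-breast tissue layout (fat with a
# fibroglandular core per side), an ellipsoidal tumor that shrinks over the
# four timepoints according to a schedule tied to the pCR label, forward
# signals from the three-component model, and Rician magnitude noise.

default_tissue_components <- function() {
  # (C1, C2, C3) per class: fat dominated by the restricted component,
  # fibroglandular by the hindered one, tumor elevated in both
  list(fat = c(0.7, 0.1, 0.1),
       fibroglandular = c(0.1, 0.6, 0.2),
       tumor = c(0.9, 0.8, 0.1))
}

#' Phantom configuration
#'
#' Describes one synthetic patient: grid geometry, acquisition b-values,
#' fixed diffusivities, per-tissue component triples, tumor ellipsoid
#' (centre and semi-axes in mm), a per-timepoint shrinkage schedule, the pCR
#' label, the Rician noise level and a seed. Shrinkage `f` at a timepoint
#' scales the ellipsoid semi-axes by `1 - f`, so `f = 1` removes the tumor
#' entirely; schedules must be non-decreasing, and a pCR patient must end at
#' `f = 1` (no residual tumor at post-treatment).
#'
#' @param grid An `image_grid`; default 64 x 64 x 16 voxels at
#'   2.5 x 2.5 x 5.0 mm (the DWI acquisition geometry).
#' @param bvalues Acquisition b-values (s/mm^2), default
#'   `c(0, 500, 1500, 4000)`.
#' @param fixed_adcs An [rsi_fixed_adcs()], default [example_fixed_adcs()].
#' @param tissue_components Named list `fat`, `fibroglandular`, `tumor` of
#'   `(C1, C2, C3)` triples.
#' @param tumor_center_mm Tumor centre (mm); default the centre of the
#'   tumor-side (left) breast.
#' @param tumor_semiaxes_mm Ellipsoid semi-axes (mm), default
#'   `c(10, 6, 6)` (2.0 cm longest diameter).
#' @param shrinkage Named numeric `pre`, `early`, `mid`, `post` in \[0, 1\].
#' @param is_pcr Logical pCR label.
#' @param noise_sigma Rician noise standard deviation on the same scale as
#'   the noiseless signal; the default 0.09 gives SNR of about 20 at b = 0
#'   in tumor tissue. Use 0 for a noiseless phantom.
#' @param seed Integer seed for the noise draws (`NULL` = leave RNG alone).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = image_grid(c(64, 64, 16), c(2.5, 2.5, 5.0)),
                           bvalues = c(0, 500, 1500, 4000),
                           fixed_adcs = example_fixed_adcs(),
                           tissue_components = default_tissue_components(),
                           tumor_center_mm = NULL,
                           tumor_semiaxes_mm = c(10, 6, 6),
                           shrinkage = c(pre = 0, early = 0.4, mid = 0.7,
                                         post = 1),
                           is_pcr = TRUE,
                           noise_sigma = 0.09,
                           seed = NULL) {
  extent <- grid$shape * grid$spacing
  if (is.null(tumor_center_mm))
    tumor_center_mm <- grid$origin + c(0.25, 0.5, 0.5) * extent
  if (any(tumor_semiaxes_mm <= 0)) stop("semi-axes must be positive")
  if (noise_sigma < 0) stop("noise sigma must be non-negative")
  if (!all(TIMEPOINTS %in% names(shrinkage)))
    stop("shrinkage needs entries pre, early, mid, post")
  shrinkage <- shrinkage[TIMEPOINTS]
  if (any(shrinkage < 0 | shrinkage > 1))
    stop("shrinkage fractions must lie in [0, 1]")
  if (is.unsorted(shrinkage))
    stop("shrinkage schedule must be non-decreasing")
  if (is_pcr && shrinkage[["post"]] < 1)
    stop("a pCR patient must reach full shrinkage at post-treatment")
  lo <- tumor_center_mm - tumor_semiaxes_mm
  hi <- tumor_center_mm + tumor_semiaxes_mm
  if (any(lo < grid$origin - grid$spacing / 2) ||
      any(hi > grid$origin + extent - grid$spacing / 2))
    stop("tumor ellipsoid extends outside the grid")
  structure(list(grid = grid, bvalues = bvalues, fixed_adcs = fixed_adcs,
                 tissue_components = tissue_components,
                 tumor_center_mm = tumor_center_mm,
                 tumor_semiaxes_mm = tumor_semiaxes_mm,
                 shrinkage = shrinkage, is_pcr = is_pcr,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_config")
}

coordinate_arrays <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

box_mask <- function(grid, frac_lo, frac_hi) {
  co <- coordinate_arrays(grid)
  extent <- grid$shape * grid$spacing
  lo <- grid$origin + frac_lo * extent
  hi <- grid$origin + frac_hi * extent
  outer(outer(co$x >= lo[1] & co$x <= hi[1],
              co$y >= lo[2] & co$y <= hi[2], `&`),
        co$z >= lo[3] & co$z <= hi[3], `&`)
}

ellipsoid_mask <- function(grid, center_mm, semiaxes_mm) {
  if (any(semiaxes_mm <= 0)) return(array(FALSE, grid$shape))
  co <- coordinate_arrays(grid)
  u <- ((co$x - center_mm[1]) / semiaxes_mm[1])^2
  v <- ((co$y - center_mm[2]) / semiaxes_mm[2])^2
  w <- ((co$z - center_mm[3]) / semiaxes_mm[3])^2
  outer(outer(u, v, `+`), w, `+`) <= 1
}

phantom_layout <- function(grid) {
  fibro <- box_mask(grid, c(0.12, 0.25, 0.25), c(0.38, 0.75, 0.75)) |
    box_mask(grid, c(0.62, 0.25, 0.25), c(0.88, 0.75, 0.75))
  control <- box_mask(grid, c(0.55, 0.10, 0.10), c(0.95, 0.90, 0.90))
  list(fibro = fibro, control = control)
}

phantom_truth_maps <- function(config, scale) {
  grid <- config$grid
  layout <- phantom_layout(grid)
  tumor <- if (scale > 0)
    ellipsoid_mask(grid, config$tumor_center_mm,
                   config$tumor_semiaxes_mm * scale)
  else array(FALSE, grid$shape)
  tc <- config$tissue_components
  assemble <- function(i) {
    m <- array(tc$fat[i], grid$shape)
    m[layout$fibro] <- tc$fibroglandular[i]
    m[tumor] <- tc$tumor[i]
    m
  }
  list(maps = component_maps(assemble(1), assemble(2), assemble(3),
                             config$fixed_adcs, grid),
       tumor_mask = tumor, control_mask = layout$control)
}

#' Simulate a DWI series from known component maps
#'
#' The noiseless signal is the exact forward model
#' `S(b) = C1 exp(-b ADC1) + C2 exp(-b ADC2) + C3 exp(-b ADC3)`. Noise is
#' Rician: the observed magnitude is `sqrt((S + g1)^2 + g2^2)` with `g1, g2`
#' independent zero-mean Gaussians of standard deviation `noise_sigma`.
#' Identical seeds give identical output.
#'
#' @param truth A [component_maps()] holding the ground-truth contributions.
#' @param bvalues b-values to simulate (s/mm^2).
#' @param noise_sigma Rician noise standard deviation (>= 0).
#' @param seed Integer seed (`NULL` = use the current RNG state).
#' @param noise `"rician"` (default) or `"gaussian"` (adds `g1` only).
#' @return A [dwi_series()].
#' @export
simulate_signal <- function(truth, bvalues, noise_sigma = 0, seed = NULL,
                            noise = c("rician", "gaussian")) {
  noise <- match.arg(noise)
  if (noise_sigma < 0) stop("noise sigma must be non-negative")
  A <- rsi_design_matrix(bvalues, truth$fixed_adcs)
  nvox <- prod(truth$grid$shape)
  C <- rbind(as.vector(truth$c1), as.vector(truth$c2), as.vector(truth$c3))
  S <- t(A %*% C)                       # nvox x nb
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    g1 <- matrix(stats::rnorm(length(S), 0, noise_sigma), nrow(S))
    if (noise == "rician") {
      g2 <- matrix(stats::rnorm(length(S), 0, noise_sigma), nrow(S))
      S <- sqrt((S + g1)^2 + g2^2)
    } else {
      S <- S + g1
    }
  }
  dwi_series(array(S, c(truth$grid$shape, length(bvalues))), bvalues,
             truth$grid)
}

#' Generate one synthetic patient
#'
#' Builds the four-timepoint study: the tumor ellipsoid is scaled by
#' `1 - shrinkage` at each timepoint, component maps are assembled from the
#' tissue classes, and a DWI series is simulated per timepoint (noise seeds
#' derived deterministically from the config seed). The cancer ROI is the
#' true pre-treatment tumor mask and the control ROI a block in the
#' contralateral breast.
#'
#' @param config A [phantom_config()].
#' @return A list with `timepoints` (named list of [dwi_series()]),
#'   `cancer_roi`, `control_roi` ([roi_mask()]) and `truth` (per-timepoint
#'   component maps, tumor masks and true longest diameters in cm).
#' @export
generate_patient <- function(config) {
  truth <- list()
  series <- list()
  control_mask <- NULL
  for (i in seq_along(TIMEPOINTS)) {
    tp <- TIMEPOINTS[i]
    scale <- 1 - config$shrinkage[[tp]]
    tm <- phantom_truth_maps(config, scale)
    control_mask <- tm$control_mask
    tp_seed <- if (is.null(config$seed)) NULL else config$seed + i
    series[[tp]] <- simulate_signal(tm$maps, config$bvalues,
                                    config$noise_sigma, seed = tp_seed)
    truth[[tp]] <- list(maps = tm$maps, tumor_mask = tm$tumor_mask,
                        diameter_cm = longest_diameter(tm$tumor_mask,
                                                       config$grid))
  }
  list(timepoints = series,
       cancer_roi = roi_mask(truth$pre$tumor_mask, config$grid, "cancer"),
       control_roi = roi_mask(control_mask, config$grid, "control"),
       truth = c(truth, list(noise_sigma = config$noise_sigma,
                             seed = config$seed,
                             is_pcr = config$is_pcr)))
}

patient_seed <- function(master_seed, i) {
  (master_seed %% 1000003L) * 1000L + i   # stays well below 2^31
}

#' Generate a synthetic cohort
#'
#' Derives per-patient seeds deterministically from the master seed and
#' assigns exactly `round(n_patients * pcr_fraction)` pCR labels. Patients
#' vary in tumor size (overall scale and mild per-axis eccentricity jitter).
#' pCR patients shrink progressively to complete disappearance at
#' post-treatment; non-pCR patients shrink by at most 20% in diameter. A
#' synthetic manually-measured DCE diameter (true diameter plus 1.5 mm
#' Gaussian reader noise, floored at 0; exactly 0 for vanished tumors) is
#' drawn per timepoint.
#'
#' @param n_patients Number of patients (>= 2), default 27.
#' @param pcr_fraction Fraction with pCR, default `10/27`.
#' @param template A [phantom_config()] supplying everything patient-
#'   independent (grid, b-values, diffusivities, tissues, noise).
#' @param seed Master integer seed.
#' @param size_range Range of the per-patient overall tumor size multiplier
#'   applied to the template semi-axes; the default `c(0.9, 2.4)` turns the
#'   2.0 cm template ellipsoid into pre-treatment longest diameters of about
#'   1.8-4.8 cm. Shrink it when simulating on small grids.
#' @return An object of class `phantom_cohort`: list of per-patient
#'   `configs`, a `labels` data frame, a `dce` table of synthetic manual
#'   diameters and `true_diameters_cm` per patient and timepoint.
#' @export
generate_cohort <- function(n_patients = 27, pcr_fraction = 10 / 27,
                            template = phantom_config(), seed = 1,
                            size_range = c(0.9, 2.4)) {
  if (n_patients < 2) stop("need at least two patients")
  if (pcr_fraction < 0 || pcr_fraction > 1)
    stop("pcr_fraction must lie in [0, 1]")
  n_pcr <- round(n_patients * pcr_fraction)
  ids <- sprintf("P%02d", seq_len(n_patients))
  is_pcr <- c(rep(TRUE, n_pcr), rep(FALSE, n_patients - n_pcr))
  configs <- list()
  dce_rows <- list()
  true_diam <- matrix(NA_real_, n_patients, length(TIMEPOINTS),
                      dimnames = list(ids, TIMEPOINTS))
  for (i in seq_len(n_patients)) {
    ps <- patient_seed(seed, i)
    set.seed(ps)
    size_scale <- stats::runif(1, size_range[1], size_range[2])
    axis_jitter <- stats::runif(3, 0.9, 1.1)
    semiaxes <- template$tumor_semiaxes_mm * size_scale * axis_jitter
    semiaxes[1] <- max(semiaxes)   # keep the first axis the major one
    if (is_pcr[i]) {
      mids <- sort(stats::runif(2, 0.2, 0.9))
      shrink <- c(pre = 0, early = mids[1], mid = mids[2], post = 1)
    } else {
      post <- stats::runif(1, 0.05, 0.2)
      mids <- sort(stats::runif(2, 0, post))
      shrink <- c(pre = 0, early = mids[1], mid = mids[2], post = post)
    }
    cfg <- phantom_config(grid = template$grid, bvalues = template$bvalues,
                          fixed_adcs = template$fixed_adcs,
                          tissue_components = template$tissue_components,
                          tumor_center_mm = template$tumor_center_mm,
                          tumor_semiaxes_mm = semiaxes,
                          shrinkage = shrink, is_pcr = is_pcr[i],
                          noise_sigma = template$noise_sigma, seed = ps)
    configs[[ids[i]]] <- cfg
    for (tp in TIMEPOINTS) {
      scale <- 1 - shrink[[tp]]
      mask <- if (scale > 0)
        ellipsoid_mask(cfg$grid, cfg$tumor_center_mm, semiaxes * scale)
      else array(FALSE, cfg$grid$shape)
      d <- longest_diameter(mask, cfg$grid)
      true_diam[i, tp] <- d
      dce <- if (d > 0) max(0, d + stats::rnorm(1, 0, 0.15)) else 0
      dce_rows[[length(dce_rows) + 1]] <-
        data.frame(patient_id = ids[i], timepoint = tp,
                   dce_diameter_cm = dce)
    }
  }
  structure(list(configs = configs,
                 labels = data.frame(patient_id = ids, pcr = is_pcr),
                 dce = do.call(rbind, dce_rows),
                 true_diameters_cm = true_diam,
                 seed = seed),
            class = "phantom_cohort")
}
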
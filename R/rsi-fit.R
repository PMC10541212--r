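# Voxel-wise three-component fixed-diffusivity fit. The signal model is
#   S(b) = C1 exp(-b * ADC1) + C2 exp(-b * ADC2) + C3 exp(-b * ADC3)
# with the per-component apparent diffusivities ADC_i fixed across voxels, so
# the fit is a (optionally non-negative) linear least-squares problem with a
# design matrix shared by every voxel.

#' Fixed per-component diffusivities
#'
#' @param adc1,adc2,adc3 Non-negative diffusivities in mm^2/s, strictly
#'   increasing: restricted < hindered < free/vascular.
#' @return An object of class `rsi_fixed_adcs`.
#' @export
rsi_fixed_adcs <- function(adc1, adc2, adc3) {
  v <- c(adc1 = as.numeric(adc1), adc2 = as.numeric(adc2),
         adc3 = as.numeric(adc3))
  if (any(!is.finite(v)) || any(v < 0))
    stop("diffusivities must be finite and non-negative")
  if (is.unsorted(v, strictly = TRUE))
    stop("diffusivities must satisfy adc1 < adc2 < adc3")
  structure(as.list(v), class = "rsi_fixed_adcs")
}

#' Example fixed diffusivity triple
#'
#' A documented example triple (mm^2/s) spanning restricted, hindered and
#' free/vascular diffusion regimes, used by the bundled phantom and the test
#' suite. The diffusivities appropriate for a given scanner protocol are a
#' required configuration input of the analysis, not a constant of this
#' package.
#'
#' @return An [rsi_fixed_adcs()] with values `1.0e-4`, `1.5e-3`, `1.0e-2`.
#' @export
example_fixed_adcs <- function() {
  rsi_fixed_adcs(1.0e-4, 1.5e-3, 1.0e-2)
}

#' Component maps container
#'
#' @param c1,c2,c3 3D non-negative arrays of unitless signal contributions.
#' @param fixed_adcs The [rsi_fixed_adcs()] used for the fit.
#' @param grid The shared `image_grid`.
#' @param normalization_factor Positive scalar, or `NULL` before
#'   normalization.
#' @return An object of class `component_maps`.
#' @export
component_maps <- function(c1, c2, c3, fixed_adcs, grid,
                           normalization_factor = NULL) {
  for (m in list(c1, c2, c3)) {
    if (!all(dim(m) == grid$shape))
      stop("component map dimensions do not match grid shape")
  }
  if (!is.null(normalization_factor) && normalization_factor <= 0)
    stop("normalization_factor must be positive")
  structure(list(c1 = c1, c2 = c2, c3 = c3, fixed_adcs = fixed_adcs,
                 grid = grid, normalization_factor = normalization_factor),
            class = "component_maps")
}

rsi_design_matrix <- function(bvalues, fixed_adcs) {
  adcs <- c(fixed_adcs$adc1, fixed_adcs$adc2, fixed_adcs$adc3)
  exp(-outer(bvalues, adcs))
}

# Exact small-scale NNLS by support enumeration: with 3 unknowns the
# non-negative least-squares optimum is the best residual among the 2^3
# unconstrained sub-fits whose coefficients come out non-negative.
nnls_enumerate <- function(A, S) {
  p <- ncol(A)
  nvox <- ncol(S)
  best_rss <- colSums(S^2)              # empty support: all coefficients 0
  best_coef <- matrix(0, p, nvox)
  subsets <- lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  for (sub in subsets) {
    As <- A[, sub, drop = FALSE]
    P <- solve(crossprod(As), t(As))
    coef <- P %*% S
    feasible <- colSums(coef < -1e-10) == 0
    if (!any(feasible)) next
    rss <- colSums((S - As %*% coef)^2)
    take <- feasible & rss < best_rss - 1e-12
    if (any(take)) {
      best_rss[take] <- rss[take]
      best_coef[, take] <- 0
      best_coef[sub, take] <- coef[, take, drop = FALSE]
    }
  }
  pmax(best_coef, 0)
}

#' Fit the three-component signal model voxel-wise
#'
#' Per voxel, finds the signal contributions `(C1, C2, C3)` minimizing the sum
#' of squared residuals between the fixed-diffusivity model and the measured
#' signal across b-values. By default the contributions are constrained to be
#' non-negative (they are physical signal fractions and noise can otherwise
#' drive them negative); set `nonneg = FALSE` for the unconstrained linear
#' fit. Noiseless forward-model signals are recovered exactly up to numerical
#' tolerance.
#'
#' @param dwi A [dwi_series()] with at least three distinct b-values.
#' @param fixed_adcs An [rsi_fixed_adcs()].
#' @param nonneg Constrain contributions to be non-negative (default `TRUE`).
#' @return A [component_maps()] (unnormalized; `normalization_factor` unset).
#' @export
fit_components <- function(dwi, fixed_adcs, nonneg = TRUE) {
  if (length(dwi$bvalues) < 3L)
    stop("at least 3 distinct b-values are required")
  if (!all(is.finite(dwi$signal)))
    stop("signal contains non-finite values")
  A <- rsi_design_matrix(dwi$bvalues, fixed_adcs)
  nvox <- prod(dwi$grid$shape)
  S <- t(matrix(dwi$signal, nrow = nvox))   # nb x nvox
  if (nonneg) {
    coef <- nnls_enumerate(A, S)
  } else {
    coef <- solve(crossprod(A), t(A)) %*% S
  }
  shp <- dwi$grid$shape
  component_maps(array(coef[1, ], shp), array(coef[2, ], shp),
                 array(coef[3, ], shp), fixed_adcs, dwi$grid)
}

#' Voxel-wise geometric mean of the restricted and hindered contributions
#'
#' @param maps A [component_maps()].
#' @return A 3D array `sqrt(c1 * c2)`.
#' @export
geometric_mean_map <- function(maps) {
  sqrt(pmax(maps$c1, 0) * pmax(maps$c2, 0))
}

#' Control-ROI normalization factor
#'
#' The per-patient intensity normalization constant: the 95th percentile of
#' the geometric mean of C1 and C2 inside the healthy contralateral control
#' ROI. The percentile uses sorted-order linear interpolation at rank
#' `(n - 1) * 0.95` ([stats::quantile()] type 7), recorded here so results
#' are reproducible.
#'
#' @param gm 3D array, typically from [geometric_mean_map()].
#' @param control A [roi_mask()] with at least one voxel and at least one
#'   positive `gm` value inside it.
#' @param prob Percentile level, default 0.95.
#' @return Positive scalar.
#' @export
normalization_factor <- function(gm, control, prob = 0.95) {
  if (!all(dim(gm) == control$grid$shape))
    stop("gm dimensions do not match control mask grid")
  vals <- gm[control$mask]
  if (length(vals) == 0L) stop("control mask is empty")
  if (!any(vals > 0)) stop("no positive values inside control mask")
  stats::quantile(vals, probs = prob, type = 7, names = FALSE)
}

#' Apply a normalization factor to component maps
#'
#' Divides all three component maps by `factor` and records it. The
#' classifier consumes only C1 and C2, but all three components are kept on
#' one common scale.
#'
#' @param maps A [component_maps()].
#' @param factor Positive scalar, typically from [normalization_factor()].
#' @return A normalized [component_maps()].
#' @export
normalize_components <- function(maps, factor) {
  if (!is.finite(factor) || factor <= 0)
    stop("normalization factor must be positive")
  component_maps(maps$c1 / factor, maps$c2 / factor, maps$c3 / factor,
                 maps$fixed_adcs, maps$grid, normalization_factor = factor)
}
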
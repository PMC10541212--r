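# Conventional mono-exponential ADC from the low-b-value shells of the same
# multi-b-value acquisition, and its mean over the pre-treatment cancer ROI.

#' Compute a conventional ADC map from low b-values
#'
#' Retains b-values below `max_b` (default 1000 s/mm^2; with the standard
#' acquisition that is b = 0 and 500) and estimates per voxel the apparent
#' diffusion coefficient as minus the ordinary least-squares slope of
#' `log(S)` versus `b`. With exactly two retained b-values this reduces to the
#' closed form `log(S(b0)/S(b1)) / (b1 - b0)`. Voxels with any non-positive
#' retained signal have no defined log-signal and are flagged undefined.
#'
#' @param dwi A [dwi_series()] with at least two b-values below `max_b`.
#' @param max_b Exclusive upper bound on retained b-values (s/mm^2).
#' @return An object of class `adc_map` with fields `adc` (3D array, mm^2/s,
#'   `NA` where undefined), `defined` (3D logical array) and `grid`.
#' @export
compute_adc_map <- function(dwi, max_b = 1000) {
  keep <- which(dwi$bvalues < max_b)
  if (length(keep) < 2L)
    stop("need at least two b-values below ", max_b, " s/mm^2")
  b <- dwi$bvalues[keep]
  nvox <- prod(dwi$grid$shape)
  S <- matrix(dwi$signal[, , , keep, drop = FALSE], nrow = nvox)
  defined <- rowSums(S <= 0 | !is.finite(S)) == 0L
  logS <- log(S)
  logS[!defined, ] <- 0
  bc <- b - mean(b)
  slope <- as.vector(logS %*% bc) / sum(bc^2)
  adc <- -slope
  adc[!defined] <- NA_real_
  structure(list(adc = array(adc, dwi$grid$shape),
                 defined = array(defined, dwi$grid$shape),
                 grid = dwi$grid),
            class = "adc_map")
}

#' Mean ADC within an ROI
#'
#' Arithmetic mean of the ADC over defined voxels of the ROI, excluding
#' undefined (zero or infinite signal) voxels and exact-zero ADC values.
#' Negative ADC estimates (possible under noise) are retained unless
#' `exclude_negative = TRUE`.
#'
#' @param adc An `adc_map` from [compute_adc_map()].
#' @param roi A non-empty [roi_mask()] on the same grid.
#' @param exclude_negative Also drop negative ADC values (default `FALSE`).
#' @return Scalar mean ADC in mm^2/s.
#' @export
mean_adc <- function(adc, roi, exclude_negative = FALSE) {
  stop_if_grid_mismatch(adc$grid, roi$grid, "ADC map and ROI")
  if (!any(roi$mask)) stop("ROI is empty")
  vals <- adc$adc[roi$mask & adc$defined]
  vals <- vals[is.finite(vals) & vals != 0]
  if (exclude_negative) vals <- vals[vals > 0]
  if (length(vals) == 0L) stop("no defined ADC voxels inside ROI")
  mean(vals)
}
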
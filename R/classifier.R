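# Pooled joint-(C1, C2) density classifier. Training voxels from all
# patients' pre-treatment cancer and control ROIs are binned on a shared 2D
# grid; the two class densities give, through Bayes' rule, a lookup table of
# the posterior probability of cancer for any (C1, C2) pair.

gaussian_smooth_1d_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  offs <- -half:half
  k <- exp(-offs^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok] / sum(k[ok])   # renormalized at the edges
  }
  M
}

bin_index <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

hist2d_counts <- function(pairs, c1_edges, c2_edges) {
  b1 <- bin_index(pairs[, 1], c1_edges)
  b2 <- bin_index(pairs[, 2], c2_edges)
  n1 <- length(c1_edges) - 1L
  n2 <- length(c2_edges) - 1L
  counts <- matrix(0, n1, n2)
  t <- table(factor(b1, levels = seq_len(n1)), factor(b2, levels = seq_len(n2)))
  counts[] <- as.numeric(t)
  counts
}

as_pair_matrix <- function(pairs, what) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop(what, " must be an n x 2 matrix of (C1, C2)")
  if (nrow(pairs) == 0L) stop(what, " training set is empty")
  if (!all(is.finite(pairs))) stop(what, " contains non-finite pairs")
  pairs
}

#' Build the posterior-probability-of-cancer lookup table
#'
#' Bins the pooled cancer and control training pairs on a common 2D grid,
#' smooths each class histogram (optional Gaussian kernel in bin units, then
#' a pseudocount in every bin), normalizes each to a probability mass
#' function, and converts the two class densities to a posterior via
#' `f_cancer * pi / (f_cancer * pi + f_control * (1 - pi))`.
#'
#' By default the bin edges span `[0, q]` per axis, where `q` is the 99.5th
#' percentile of the pooled training values on that axis; out-of-range values
#' are clamped into the edge bins both at training and at lookup time.
#'
#' @param cancer_pairs,control_pairs n x 2 matrices of normalized `(C1, C2)`
#'   training values.
#' @param bins Number of bins per axis (default 128).
#' @param prior_cancer Prior probability of cancer `pi` in (0, 1); default
#'   0.5, which makes the posterior a pure density ratio.
#' @param smoothing_sigma_bins Gaussian smoothing standard deviation in bin
#'   units; 0 disables smoothing. Default 1.
#' @param pseudocount Smoothing mass expressed as a fraction of each class's
#'   training total spread uniformly over all bins (default 0.5, i.e. half a
#'   class-count's worth of uniform mass). Scaling by the class total keeps
#'   the two class floors equal regardless of how unbalanced the training
#'   ROIs are, so bins never seen in training fall back to the prior.
#' @param c1_edges,c2_edges Optional explicit bin edges (strictly
#'   increasing); override `bins` and the percentile-based span.
#' @return An object of class `posterior_lookup`.
#' @export
build_lookup <- function(cancer_pairs, control_pairs, bins = 128L,
                         prior_cancer = 0.5, smoothing_sigma_bins = 1,
                         pseudocount = 0.5,
                         c1_edges = NULL, c2_edges = NULL) {
  cancer_pairs <- as_pair_matrix(cancer_pairs, "cancer")
  control_pairs <- as_pair_matrix(control_pairs, "control")
  if (prior_cancer <= 0 || prior_cancer >= 1)
    stop("prior_cancer must lie strictly inside (0, 1)")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (smoothing_sigma_bins < 0) stop("smoothing sigma must be non-negative")
  pooled <- rbind(cancer_pairs, control_pairs)
  default_edges <- function(x) {
    q <- stats::quantile(x, 0.995, type = 7, names = FALSE)
    if (q <= 0) q <- max(x, 1e-6)
    if (q <= 0) q <- 1e-6
    seq(0, q, length.out = bins + 1L)
  }
  if (is.null(c1_edges)) c1_edges <- default_edges(pooled[, 1])
  if (is.null(c2_edges)) c2_edges <- default_edges(pooled[, 2])
  if (is.unsorted(c1_edges, strictly = TRUE) ||
      is.unsorted(c2_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  class_density <- function(pairs) {
    counts <- hist2d_counts(pairs, c1_edges, c2_edges)
    if (smoothing_sigma_bins > 0) {
      G1 <- gaussian_smooth_1d_matrix(nrow(counts), smoothing_sigma_bins)
      G2 <- gaussian_smooth_1d_matrix(ncol(counts), smoothing_sigma_bins)
      counts <- G1 %*% counts %*% t(G2)
    }
    # pseudocount scaled by the class total: `pseudocount` is the fraction
    # of each class's mass spread uniformly over the grid. A flat per-bin
    # count would hand the smaller class a higher floor density after
    # normalization, pushing every EMPTY bin toward that class; with the
    # scaled form, bins unseen in training sit exactly at the prior.
    counts <- counts + pseudocount * nrow(pairs) / length(counts)
    counts / sum(counts)
  }
  f_cancer <- class_density(cancer_pairs)
  f_control <- class_density(control_pairs)
  pi1 <- prior_cancer
  posterior <- f_cancer * pi1 / (f_cancer * pi1 + f_control * (1 - pi1))
  structure(list(c1_edges = c1_edges, c2_edges = c2_edges,
                 posterior = posterior, prior_cancer = prior_cancer,
                 smoothing_sigma_bins = smoothing_sigma_bins,
                 pseudocount = pseudocount,
                 training_counts = c(cancer = nrow(cancer_pairs),
                                     control = nrow(control_pairs))),
            class = "posterior_lookup")
}

#' Voxel-wise posterior probability map
#'
#' Assigns to every voxel the posterior of the lookup bin containing its
#' `(C1, C2)` pair; values beyond the edges are clamped into the nearest edge
#' bin. The component maps must be normalized with the same convention as the
#' lookup's training data.
#'
#' @param maps A normalized [component_maps()].
#' @param lookup A [build_lookup()] table.
#' @return An object of class `probability_map` with fields `prob` (3D array
#'   in \[0, 1\]) and `grid`.
#' @export
posterior_map <- function(maps, lookup) {
  if (!all(dim(maps$c1) == dim(maps$c2)))
    stop("grid mismatch between c1 and c2")
  b1 <- bin_index(as.vector(maps$c1), lookup$c1_edges)
  b2 <- bin_index(as.vector(maps$c2), lookup$c2_edges)
  prob <- array(lookup$posterior[cbind(b1, b2)], dim = dim(maps$c1))
  structure(list(prob = prob, grid = maps$grid), class = "probability_map")
}

#' Threshold a probability map
#'
#' @param prob A `probability_map` (or bare 3D array of probabilities).
#' @param threshold Scalar in \[0, 1\]; voxels with probability strictly
#'   greater are classified as cancer. Default 0.5.
#' @return A 3D logical array.
#' @export
classify_map <- function(prob, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  p <- if (inherits(prob, "probability_map")) prob$prob else prob
  p > threshold
}

#' Serialize a posterior lookup table to JSON
#'
#' @param lookup A `posterior_lookup`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_lookup <- function(lookup, path) {
  obj <- list(c1_edges = lookup$c1_edges, c2_edges = lookup$c2_edges,
              posterior = lookup$posterior,
              prior_cancer = lookup$prior_cancer,
              smoothing_sigma_bins = lookup$smoothing_sigma_bins,
              pseudocount = lookup$pseudocount,
              training_counts = as.list(lookup$training_counts))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a posterior lookup table from JSON
#'
#' @param path Path written by [save_lookup()].
#' @return A `posterior_lookup`.
#' @export
load_lookup <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(c1_edges = as.numeric(obj$c1_edges),
                 c2_edges = as.numeric(obj$c2_edges),
                 posterior = as.matrix(obj$posterior),
                 prior_cancer = obj$prior_cancer,
                 smoothing_sigma_bins = obj$smoothing_sigma_bins,
                 pseudocount = obj$pseudocount,
                 training_counts = unlist(obj$training_counts)),
            class = "posterior_lookup")
}
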
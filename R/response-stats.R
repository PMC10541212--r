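# Endpoint statistics for the response study: relative-change metrics, ROC
# AUC (Mann-Whitney form), operating points, exact binomial CIs, exact
# McNemar and DeLong paired tests, and whole-cohort evaluation tables.
# Throughout, the positive class is non-pCR (residual tumor at surgery).

#' Relative change from the pre-treatment value
#'
#' `(value_t - value_pre) / value_pre`. For non-negative sizes the floor is
#' -1.0, attained when a lesion disappears completely.
#'
#' @param value_t Value at the later timepoint.
#' @param value_pre Non-zero pre-treatment value.
#' @return The relative change (vectorized).
#' @export
relative_change <- function(value_t, value_pre) {
  if (any(value_pre == 0)) stop("pre-treatment value must be non-zero")
  (value_t - value_pre) / value_pre
}

orient_scores <- function(scores, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (direction == "lower") -scores else scores
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels have different lengths")
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  labels
}

#' ROC area under the curve (Mann-Whitney estimate)
#'
#' The probability that a random positive scores higher than a random
#' negative, with ties counted 1/2 — equal to the trapezoidal area under the
#' empirical ROC curve. `direction = "lower"` declares that lower scores
#' indicate the positive class (used for ADC, where response is expected to
#' raise the value).
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive = non-pCR.
#' @param direction `"higher"` (default) or `"lower"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, direction = c("higher", "lower")) {
  labels <- check_scores_labels(scores, labels)
  s <- orient_scores(scores, direction)
  r <- rank(s)                      # midranks handle ties as 1/2
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(lapply(v, as.integer), class = "confusion_counts")
}

counts_at_threshold <- function(oriented, labels, threshold) {
  pred <- oriented > threshold
  confusion_counts(sum(pred & labels), sum(!pred & labels),
                   sum(pred & !labels), sum(!pred & !labels))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' @param counts A [confusion_counts()].
#' @return Named numeric vector `(sensitivity, specificity, accuracy)`.
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    if (tp + fn == 0 || fp + tn == 0) stop("empty class margin")
    c(sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      accuracy = (tp + tn) / (tp + fn + fp + tn))
  })
}

threshold_candidates <- function(oriented) {
  s <- sort(unique(oriented))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric()
  c(-Inf, mids, Inf)
}

scan_operating_points <- function(scores, labels, direction) {
  labels <- check_scores_labels(scores, labels)
  oriented <- orient_scores(scores, direction)
  cands <- threshold_candidates(oriented)
  rows <- lapply(cands, function(t) {
    cc <- counts_at_threshold(oriented, labels, t)
    m <- confusion_metrics(cc)
    list(threshold = t, counts = cc, metrics = m,
         n_positive_calls = cc$tp + cc$fp)
  })
  list(rows = rows, labels = labels, direction = direction)
}

pick_row <- function(rows, key) {
  best <- NULL
  for (r in rows) if (is.null(best) || key(r, best)) best <- r
  best
}

restore_threshold <- function(threshold, direction) {
  if (direction == "lower") -threshold else threshold
}

#' Operating point maximizing accuracy
#'
#' Scans the candidate thresholds (midpoints between adjacent distinct
#' scores, plus the two degenerate classify-all/none thresholds) and returns
#' the one with the highest accuracy. Accuracy ties are broken toward higher
#' specificity, then toward the more conservative rule (fewer positive
#' calls). With `direction = "higher"` a case is called positive when its
#' score exceeds the threshold; with `"lower"`, when it falls below.
#'
#' @inheritParams roc_auc
#' @return List with `threshold` (on the original score scale), `counts`
#'   (a [confusion_counts()]) and `metrics`.
#' @export
best_accuracy_operating_point <- function(scores, labels,
                                          direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  sc <- scan_operating_points(scores, labels, direction)
  best <- pick_row(sc$rows, function(r, b) {
    if (r$metrics["accuracy"] != b$metrics["accuracy"])
      return(r$metrics["accuracy"] > b$metrics["accuracy"])
    if (r$metrics["specificity"] != b$metrics["specificity"])
      return(r$metrics["specificity"] > b$metrics["specificity"])
    r$n_positive_calls < b$n_positive_calls
  })
  list(threshold = restore_threshold(best$threshold, direction),
       counts = best$counts, metrics = best$metrics)
}

#' Operating point maximizing sensitivity at constrained specificity
#'
#' Among thresholds achieving at least `min_specificity`, returns the one
#' with the highest sensitivity (ties toward higher specificity, then fewer
#' positive calls). The classify-none threshold always satisfies the
#' constraint, so a degenerate sensitivity-0 point is returned when nothing
#' better exists.
#'
#' @inheritParams roc_auc
#' @param min_specificity Specificity floor, default 0.90.
#' @return As [best_accuracy_operating_point()].
#' @export
spec_constrained_operating_point <- function(scores, labels,
                                             direction = c("higher", "lower"),
                                             min_specificity = 0.90) {
  direction <- match.arg(direction)
  if (min_specificity < 0 || min_specificity > 1)
    stop("min_specificity must lie in [0, 1]")
  sc <- scan_operating_points(scores, labels, direction)
  rows <- Filter(function(r) r$metrics["specificity"] >= min_specificity,
                 sc$rows)
  best <- pick_row(rows, function(r, b) {
    if (r$metrics["sensitivity"] != b$metrics["sensitivity"])
      return(r$metrics["sensitivity"] > b$metrics["sensitivity"])
    if (r$metrics["specificity"] != b$metrics["specificity"])
      return(r$metrics["specificity"] > b$metrics["specificity"])
    r$n_positive_calls < b$n_positive_calls
  })
  list(threshold = restore_threshold(best$threshold, direction),
       counts = best$counts, metrics = best$metrics)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles; the lower bound is exactly 0
#' when no successes are observed and the upper bound exactly 1 when all
#' trials succeed.
#'
#' @param successes,n Integer counts, `0 <= successes <= n`, `n >= 1`.
#' @param alpha Two-sided error level (default 0.05 for a 95% interval).
#' @return Named numeric vector `(lower, upper)`.
#' @export
clopper_pearson_ci <- function(successes, n, alpha = 0.05) {
  if (n < 1 || successes < 0 || successes > n)
    stop("invalid counts")
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Exact McNemar test on discordant pairs
#'
#' Compares the marginal classification rates of two diagnostic methods on
#' paired subjects via the exact two-sided binomial test on the discordant
#' counts: `p = min(1, 2 * P(X <= min(b, c)))` with
#' `X ~ Binomial(b + c, 1/2)`; no discordance gives p = 1.
#'
#' @param discordant_b,discordant_c Non-negative discordant-pair counts.
#' @param alpha Significance level recorded in the result (default 0.025,
#'   reflecting correction for two primary outcomes).
#' @param method `"exact"` (default; appropriate for small cohorts) or
#'   `"chisq"` for the classical uncorrected chi-square approximation.
#' @return An object of class `paired_test_result`.
#' @export
mcnemar_exact <- function(discordant_b, discordant_c, alpha = 0.025,
                          method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (discordant_b < 0 || discordant_c < 0) stop("counts must be non-negative")
  n <- discordant_b + discordant_c
  if (method == "chisq") {
    stat <- if (n == 0) 0 else (discordant_b - discordant_c)^2 / n
    p <- if (n == 0) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
    return(structure(list(test_name = "mcnemar_chisq", statistic = stat,
                          p_value = p, alpha = alpha,
                          discordant = c(b = discordant_b, c = discordant_c)),
                     class = "paired_test_result"))
  }
  p <- if (n == 0) 1 else
    min(1, 2 * stats::pbinom(min(discordant_b, discordant_c), n, 0.5))
  structure(list(test_name = "mcnemar_exact",
                 statistic = min(discordant_b, discordant_c),
                 p_value = p, alpha = alpha,
                 discordant = c(b = discordant_b, c = discordant_c)),
            class = "paired_test_result")
}

delong_placements <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' DeLong test for two correlated ROC curves
#'
#' Computes both AUCs via placement values, estimates the covariance of the
#' paired AUC estimates with the DeLong structural-component estimator, and
#' tests `AUC_a = AUC_b` with a two-sided normal z-test. Per-curve variances
#' and 95% Wald intervals are exposed.
#'
#' @param scores_a,scores_b Paired score vectors on identical subjects.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive.
#' @param alpha Significance level recorded in the result (default 0.025).
#' @return An object of class `paired_test_result` with fields `auc_a`,
#'   `auc_b`, `var_a`, `var_b`, `ci_a`, `ci_b`, `statistic` (z), `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels, alpha = 0.025) {
  labels <- check_scores_labels(scores_a, labels)
  if (length(scores_b) != length(scores_a))
    stop("scores_a and scores_b must be paired")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels)
  n <- sum(!labels)
  S10 <- stats::cov(cbind(pa$v10, pb$v10))
  S01 <- stats::cov(cbind(pa$v01, pb$v01))
  if (m < 2 || n < 2) stop("need at least two subjects per class")
  var_a <- S10[1, 1] / m + S01[1, 1] / n
  var_b <- S10[2, 2] / m + S01[2, 2] / n
  var_diff <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  dauc <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(dauc) > 1e-12)
      stop("zero variance estimate with unequal AUCs")
    z <- 0
    p <- 1
  } else {
    z <- dauc / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  wald <- function(auc, v) {
    half <- stats::qnorm(0.975) * sqrt(max(v, 0))
    c(lower = max(0, auc - half), upper = min(1, auc + half))
  }
  structure(list(test_name = "delong", statistic = z, p_value = p,
                 alpha = alpha, auc_a = pa$auc, auc_b = pb$auc,
                 delta_auc = dauc, var_a = var_a, var_b = var_b,
                 var_delta = var_diff,
                 ci_a = wald(pa$auc, var_a), ci_b = wald(pb$auc, var_b)),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (alpha = %g)\n",
              x$test_name, x$statistic, x$p_value, x$alpha))
  invisible(x)
}

#' AUC with a DeLong-variance Wald confidence interval
#'
#' @inheritParams roc_auc
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auc` and `ci` (`lower`, `upper`).
#' @export
auc_with_ci <- function(scores, labels, direction = c("higher", "lower"),
                        conf_level = 0.95) {
  labels <- check_scores_labels(scores, labels)
  s <- orient_scores(scores, direction)
  pl <- delong_placements(s, labels)
  m <- sum(labels)
  n <- sum(!labels)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  half <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(max(v, 0))
  list(auc = pl$auc,
       ci = c(lower = max(0, pl$auc - half), upper = min(1, pl$auc + half)))
}

#' Round half away from zero
#'
#' Display rounding used by the result tables (R's [round()] rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
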
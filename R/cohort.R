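# Cohort container: per-patient per-timepoint measurements plus the binary
# pathology endpoint, and the Table-style evaluation over modalities and
# timepoints.

TIMEPOINTS <- c("pre", "early", "mid", "post")
MODALITY_COLUMNS <- c(rsi = "rsi_diameter_cm", dce = "dce_diameter_cm",
                      adc = "mean_adc")

#' Assemble a cohort dataset
#'
#' @param records Data frame with columns `patient_id`, `timepoint` (one of
#'   `"pre"`, `"early"`, `"mid"`, `"post"`), `rsi_diameter_cm`,
#'   `dce_diameter_cm`, `mean_adc` (measurement columns may contain `NA`).
#'   At most one record per (patient, timepoint).
#' @param labels Data frame with columns `patient_id` and `pcr` (logical or
#'   0/1); every patient in `records` must be labelled. The positive class of
#'   every downstream analysis is non-pCR.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(records, labels) {
  records <- as.data.frame(records)
  labels <- as.data.frame(labels)
  needed <- c("patient_id", "timepoint", MODALITY_COLUMNS)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(records$timepoint %in% TIMEPOINTS))
    stop("timepoint must be one of: ", paste(TIMEPOINTS, collapse = ", "))
  if (anyDuplicated(records[c("patient_id", "timepoint")]))
    stop("duplicate (patient, timepoint) records")
  if (!all(c("patient_id", "pcr") %in% names(labels)))
    stop("labels needs columns patient_id and pcr")
  if (anyDuplicated(labels$patient_id)) stop("duplicate patient labels")
  unlabelled <- setdiff(records$patient_id, labels$patient_id)
  if (length(unlabelled))
    stop("patients without a pCR label: ", paste(unlabelled, collapse = ", "))
  labels$pcr <- as.logical(labels$pcr)
  if (anyNA(labels$pcr)) stop("pCR labels must be binary")
  structure(list(records = records, labels = labels),
            class = "cohort_dataset")
}

#' Read a cohort CSV
#'
#' Expects columns `patient_id, timepoint, rsi_diameter_cm, dce_diameter_cm,
#' mean_adc, pcr` (the label repeated on each of a patient's rows).
#'
#' @param path CSV path.
#' @return A [cohort_dataset()].
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- unique(df[c("patient_id", "pcr")])
  cohort_dataset(df[setdiff(names(df), "pcr")], labels)
}

#' Write a cohort CSV
#'
#' @param dataset A [cohort_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(dataset, path) {
  df <- merge(dataset$records, dataset$labels, by = "patient_id")
  df <- df[order(df$patient_id, match(df$timepoint, TIMEPOINTS)), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

wide_timepoint <- function(dataset, tp, column) {
  rec <- dataset$records[dataset$records$timepoint == tp, ]
  out <- rec[[column]]
  names(out) <- rec$patient_id
  out[!is.na(out)]
}

modality_block <- function(scores, labels, direction, alpha,
                           min_specificity) {
  auc <- auc_with_ci(scores, labels, direction)
  best <- best_accuracy_operating_point(scores, labels, direction)
  spec90 <- spec_constrained_operating_point(scores, labels, direction,
                                             min_specificity)
  with_ci <- function(successes, n, est) {
    list(estimate = est, ci = clopper_pearson_ci(successes, n))
  }
  cc <- best$counts
  n_pos <- cc$tp + cc$fn
  n_neg <- cc$fp + cc$tn
  list(n = length(scores), n_positive = n_pos, n_negative = n_neg,
       direction = direction,
       auc = auc$auc, auc_ci = auc$ci,
       threshold = best$threshold, counts = cc,
       sensitivity = with_ci(cc$tp, n_pos, best$metrics[["sensitivity"]]),
       specificity = with_ci(cc$tn, n_neg, best$metrics[["specificity"]]),
       accuracy = with_ci(cc$tp + cc$tn, n_pos + n_neg,
                          best$metrics[["accuracy"]]),
       spec90 = list(threshold = spec90$threshold, counts = spec90$counts,
                     sensitivity = spec90$metrics[["sensitivity"]],
                     specificity = spec90$metrics[["specificity"]],
                     accuracy = spec90$metrics[["accuracy"]]))
}

predicted_positive <- function(scores, threshold, direction) {
  if (direction == "lower") scores < threshold else scores > threshold
}

pairwise_comparisons <- function(score_list, labels, directions, blocks,
                                 alpha) {
  mods <- names(score_list)
  out <- list()
  if (length(mods) < 2) return(out)
  for (i in seq_len(length(mods) - 1)) {
    for (j in seq(i + 1, length(mods))) {
      a <- mods[i]; b <- mods[j]
      sa <- orient_scores(score_list[[a]], directions[[a]])
      sb <- orient_scores(score_list[[b]], directions[[b]])
      dl <- delong_test(sa, sb, labels, alpha = alpha)
      pred_a <- predicted_positive(score_list[[a]], blocks[[a]]$threshold,
                                   directions[[a]])
      pred_b <- predicted_positive(score_list[[b]], blocks[[b]]$threshold,
                                   directions[[b]])
      # McNemar separately on true positives (sensitivity) and true
      # negatives (specificity)
      mc <- function(subset) {
        mcnemar_exact(sum(pred_a[subset] & !pred_b[subset]),
                      sum(!pred_a[subset] & pred_b[subset]), alpha = alpha)
      }
      out[[paste(a, b, sep = "_vs_")]] <-
        list(delong = dl,
             mcnemar_sensitivity = mc(labels),
             mcnemar_specificity = mc(!labels))
    }
  }
  out
}

#' Evaluate a cohort against the pathology endpoint
#'
#' Produces the absolute post-treatment block (the three modalities scored by
#' their post-treatment values) and, for patients imaged at all four
#' timepoints, relative-change blocks at the early, mid and post timepoints.
#' Each block carries the AUC with a DeLong-variance Wald CI, the
#' best-accuracy operating point with exact binomial CIs on sensitivity,
#' specificity and accuracy, the operating point constrained to specificity
#' >= `min_specificity`, and pairwise DeLong / exact McNemar comparisons
#' between modalities. Tumor sizes are scored with larger = more likely
#' non-pCR; mean ADC with lower = more likely non-pCR (the a priori
#' assumption that ADC rises with response).
#'
#' @param dataset A [cohort_dataset()].
#' @param alpha Significance level recorded on the paired tests
#'   (default 0.025, correcting for two primary outcomes).
#' @param min_specificity Specificity floor for the constrained operating
#'   point (default 0.90).
#' @param directions Named list mapping `rsi`, `dce`, `adc` to `"higher"` or
#'   `"lower"`.
#' @return An object of class `cohort_evaluation`: a nested list with
#'   elements `absolute` and `delta` (the latter with `early`, `mid`,
#'   `post`).
#' @export
evaluate_cohort <- function(dataset, alpha = 0.025, min_specificity = 0.90,
                            directions = list(rsi = "higher", dce = "higher",
                                              adc = "lower")) {
  labels_of <- function(ids) {
    lab <- dataset$labels$pcr[match(ids, dataset$labels$patient_id)]
    !lab   # positive class = non-pCR
  }
  block_set <- function(score_list) {
    ids <- Reduce(intersect, lapply(score_list, names))
    if (length(ids) == 0) stop("no complete cases")
    y <- labels_of(ids)
    if (!any(y) || all(y)) stop("cohort contains a single class")
    score_list <- lapply(score_list, function(s) s[ids])
    blocks <- lapply(names(score_list), function(m) {
      modality_block(score_list[[m]], y, directions[[m]], alpha,
                     min_specificity)
    })
    names(blocks) <- names(score_list)
    list(n = length(ids), patients = ids, modalities = blocks,
         comparisons = pairwise_comparisons(score_list, y, directions,
                                            blocks, alpha))
  }
  # absolute post-treatment values
  post_scores <- lapply(MODALITY_COLUMNS, wide_timepoint,
                        dataset = dataset, tp = "post")
  absolute <- block_set(post_scores)
  # relative change, restricted to patients with all four scans
  per_tp <- lapply(TIMEPOINTS, function(tp) {
    lapply(MODALITY_COLUMNS, wide_timepoint, dataset = dataset, tp = tp)
  })
  names(per_tp) <- TIMEPOINTS
  complete_ids <- Reduce(intersect, lapply(TIMEPOINTS, function(tp) {
    Reduce(intersect, lapply(per_tp[[tp]], names))
  }))
  delta <- NULL
  if (length(complete_ids) >= 2) {
    delta_at <- function(tp) {
      score_list <- lapply(names(MODALITY_COLUMNS), function(m) {
        pre <- per_tp[["pre"]][[m]][complete_ids]
        now <- per_tp[[tp]][[m]][complete_ids]
        ok <- pre != 0
        relative_change(now[ok], pre[ok])
      })
      names(score_list) <- names(MODALITY_COLUMNS)
      block_set(score_list)
    }
    delta <- lapply(c(early = "early", mid = "mid", post = "post"), delta_at)
  }
  structure(list(alpha = alpha, min_specificity = min_specificity,
                 directions = directions, absolute = absolute, delta = delta),
            class = "cohort_evaluation")
}

#' Flatten a cohort evaluation into a table
#'
#' One row per (block, modality) with the headline statistics, rounded to two
#' decimals (half away from zero) for display alongside the unrounded values.
#'
#' @param evaluation A `cohort_evaluation` from [evaluate_cohort()].
#' @return A data frame.
#' @export
evaluation_table <- function(evaluation) {
  rows <- list()
  add_block <- function(name, set) {
    for (m in names(set$modalities)) {
      b <- set$modalities[[m]]
      rows[[length(rows) + 1]] <<- data.frame(
        block = name, modality = m, n = b$n,
        threshold = b$threshold, auc = b$auc,
        auc_lower = b$auc_ci[["lower"]], auc_upper = b$auc_ci[["upper"]],
        sensitivity = b$sensitivity$estimate,
        sens_lower = b$sensitivity$ci[["lower"]],
        sens_upper = b$sensitivity$ci[["upper"]],
        specificity = b$specificity$estimate,
        spec_lower = b$specificity$ci[["lower"]],
        spec_upper = b$specificity$ci[["upper"]],
        accuracy = b$accuracy$estimate,
        acc_lower = b$accuracy$ci[["lower"]],
        acc_upper = b$accuracy$ci[["upper"]],
        sens_90 = b$spec90$sensitivity, acc_90 = b$spec90$accuracy)
    }
  }
  add_block("absolute_post", evaluation$absolute)
  for (tp in names(evaluation$delta))
    add_block(paste0("delta_", tp), evaluation$delta[[tp]])
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
  out[paste0(names(out)[num], "_2dp")] <- lapply(out[num], round_half_up)
  out
}
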
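# helpers to build small cohorts by hand
counts_from <- function(block) {
  c(tp = block$counts$tp, fn = block$counts$fn,
    fp = block$counts$fp, tn = block$counts$tn)
}

make_records <- function(ids, tps, rsi, dce, adc) {
  data.frame(patient_id = rep(ids, each = length(tps)),
             timepoint = rep(tps, times = length(ids)),
             rsi_diameter_cm = rsi, dce_diameter_cm = dce, mean_adc = adc)
}

test_that("cohort_dataset validates labels and uniqueness", {
  rec <- make_records(c("a", "b"), c("pre", "post"), 1:4, 1:4, rep(1e-3, 4))
  lab <- data.frame(patient_id = c("a", "b"), pcr = c(TRUE, FALSE))
  ds <- cohort_dataset(rec, lab)
  expect_s3_class(ds, "cohort_dataset")
  expect_error(cohort_dataset(rbind(rec, rec[1, ]), lab), "duplicate")
  expect_error(cohort_dataset(rec, lab[1, , drop = FALSE]), "without a pCR")
  rec_bad <- rec; rec_bad$timepoint[1] <- "week3"
  expect_error(cohort_dataset(rec_bad, lab), "timepoint")
})

test_that("a separable cohort yields AUC 1 in every block", {
  ids <- sprintf("p%02d", 1:12)
  pcr <- c(rep(TRUE, 5), rep(FALSE, 7))
  tps <- c("pre", "early", "mid", "post")
  rows <- list()
  for (i in seq_along(ids)) {
    pre_size <- 3
    # non-pCR keeps size, pCR shrinks hard; ADC rises only under response
    fac <- if (pcr[i]) c(1, 0.6, 0.3, 0) else c(1, 0.95, 0.9, 0.85)
    adc <- if (pcr[i]) c(1, 1.4, 1.8, 2.2) * 1e-3 else rep(1.05e-3, 4) + i * 1e-6
    rows[[i]] <- data.frame(patient_id = ids[i], timepoint = tps,
                            rsi_diameter_cm = pre_size * fac,
                            dce_diameter_cm = pre_size * fac + 0.1 * (i %% 2),
                            mean_adc = adc)
  }
  ds <- cohort_dataset(do.call(rbind, rows),
                       data.frame(patient_id = ids, pcr = pcr))
  ev <- evaluate_cohort(ds)
  for (m in c("rsi", "dce", "adc")) {
    expect_equal(ev$absolute$modalities[[m]]$auc, 1)
    expect_equal(ev$absolute$modalities[[m]]$accuracy$estimate, 1)
  }
  for (tp in c("early", "mid", "post"))
    expect_equal(ev$delta[[tp]]$modalities$rsi$auc, 1)
  # complete disappearance floors the relative change at -1
  expect_lte(ev$delta$post$modalities$rsi$threshold, 0)
})

test_that("a hand-built 27-patient cohort crossing 0.75 cm reproduces known counts", {
  # 17 non-pCR: 12 above the 0.75 cm threshold (TP), 5 at/below (FN);
  # 10 pCR: 1 above (FP), 9 below (TN). Small residual sizes are mirrored
  # between the FN and TN groups so that lowering the threshold trades a
  # false negative for a false positive one-for-one: the high threshold is
  # then the unique accuracy maximum up to specificity-favouring ties.
  ids <- sprintf("p%02d", 1:27)
  pcr <- c(rep(FALSE, 17), rep(TRUE, 10))
  rsi_post <- c(seq(0.8, 3.0, length.out = 12),  # TP
                c(0.2, 0.3, 0.4, 0.5, 0.6),      # FN
                2.5,                             # FP
                c(0, 0, 0, 0, 0.2, 0.3, 0.4, 0.5, 0.6))  # TN
  rec <- data.frame(patient_id = ids, timepoint = "post",
                    rsi_diameter_cm = rsi_post,
                    dce_diameter_cm = rsi_post,   # secondary modality copy
                    mean_adc = 1e-3 + 1e-5 * seq_along(ids))
  ds <- cohort_dataset(rec, data.frame(patient_id = ids, pcr = pcr))
  ev <- evaluate_cohort(ds)
  rsi <- ev$absolute$modalities$rsi
  cc <- counts_from(rsi)
  expect_equal(cc, c(tp = 12, fn = 5, fp = 1, tn = 9))
  expect_equal(round_half_up(rsi$sensitivity$estimate), 0.71)
  expect_equal(round_half_up(rsi$specificity$estimate), 0.90)
  expect_equal(round_half_up(rsi$accuracy$estimate), 0.78)
  expect_true(rsi$threshold > 0.6 && rsi$threshold < 0.8)

  # permuting patient order changes nothing
  perm <- sample(27)
  ds2 <- cohort_dataset(rec[perm, ],
                        data.frame(patient_id = ids, pcr = pcr)[sample(27), ])
  ev2 <- evaluate_cohort(ds2)
  expect_equal(ev2$absolute$modalities$rsi$auc, rsi$auc)
  expect_equal(counts_from(ev2$absolute$modalities$rsi), cc)
  expect_equal(ev2$absolute$comparisons$rsi_vs_dce$delong$p_value,
               ev$absolute$comparisons$rsi_vs_dce$delong$p_value)
})

test_that("delta analyses restrict to patients imaged at all four timepoints", {
  ids <- sprintf("p%02d", 1:8)
  pcr <- rep(c(TRUE, FALSE), 4)
  tps <- c("pre", "early", "mid", "post")
  rows <- list()
  for (i in seq_along(ids)) {
    keep <- if (i <= 2) c("pre", "post") else tps   # two incomplete patients
    fac <- if (pcr[i]) c(1, 0.5, 0.2, 0) else c(1, 0.9, 0.85, 0.8)
    names(fac) <- tps
    # ADC rises under response (pCR), stays put otherwise
    adc_rise <- if (pcr[i]) c(0, 0.3, 0.6, 0.9) else c(0, 0.02, 0.04, 0.05)
    names(adc_rise) <- tps
    rows[[i]] <- data.frame(patient_id = ids[i], timepoint = keep,
                            rsi_diameter_cm = 2 * fac[keep],
                            dce_diameter_cm = 2 * fac[keep],
                            mean_adc = 1e-3 + adc_rise[keep] * 1e-3 + i * 1e-6)
  }
  ds <- cohort_dataset(do.call(rbind, rows),
                       data.frame(patient_id = ids, pcr = pcr))
  ev <- evaluate_cohort(ds)
  expect_equal(ev$absolute$n, 8)
  expect_equal(ev$delta$early$n, 6)
  expect_setequal(ev$delta$early$patients, ids[3:8])
})

test_that("cohort CSVs round-trip and the evaluation table flattens cleanly", {
  ids <- sprintf("p%02d", 1:10)
  pcr <- rep(c(TRUE, FALSE), 5)
  rec <- make_records(ids, c("pre", "post"),
                      rsi = rep(c(2, 0.2, 2, 1.8), 5),
                      dce = rep(c(2.2, 0.3, 2.1, 2.0), 5),
                      adc = rep(c(1e-3, 2e-3, 1e-3, 1.1e-3), 5))
  ds <- cohort_dataset(rec, data.frame(patient_id = ids, pcr = pcr))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(ds, f)
  back <- read_cohort_csv(f)
  expect_setequal(back$records$patient_id, ds$records$patient_id)
  m <- merge(back$records, ds$records, by = c("patient_id", "timepoint"))
  expect_equal(m$rsi_diameter_cm.x, m$rsi_diameter_cm.y)
  expect_equal(back$labels[order(back$labels$patient_id), "pcr"],
               ds$labels[order(ds$labels$patient_id), "pcr"])

  ev <- evaluate_cohort(ds)
  tab <- evaluation_table(ev)
  expect_true(all(c("block", "modality", "auc", "sens_90") %in% names(tab)))
  expect_equal(nrow(tab), 3)   # only the absolute block: no early/mid scans
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
})
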
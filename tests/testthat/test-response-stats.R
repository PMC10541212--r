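test_that("relative change handles the complete-response floor", {
  expect_equal(relative_change(5, 5), 0)
  expect_equal(relative_change(0, 4), -1)
  expect_equal(relative_change(3, 2), 0.5)
  expect_equal(relative_change(c(2, 0), c(4, 4)), c(-0.5, -1))
  expect_error(relative_change(1, 0), "non-zero")
})

test_that("roc_auc is the Mann-Whitney probability with ties at 1/2", {
  y <- c(rep(TRUE, 3), rep(FALSE, 3))
  expect_equal(roc_auc(c(4, 5, 6, 1, 2, 3), y), 1)
  expect_equal(roc_auc(rep(2, 6), y), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6), y, direction = "lower"), 1)

  set.seed(101)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    scores <- sample(1:8, n, replace = TRUE)   # heavy ties
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
    # complement identity needs tie-free scores
    sf <- rnorm(n)
    expect_equal(roc_auc(sf, labels) + roc_auc(-sf, labels), 1)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(roc_auc(1:3, c(TRUE, FALSE)), "lengths")
})

test_that("operating points match exhaustive scans and break ties conservatively", {
  y <- c(rep(TRUE, 4), rep(FALSE, 4))
  sep <- best_accuracy_operating_point(c(5, 6, 7, 8, 1, 2, 3, 4), y)
  expect_equal(unname(sep$metrics["accuracy"]), 1)

  # degenerate all-equal scores: majority class call
  deg <- best_accuracy_operating_point(rep(1, 7), c(TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(unname(deg$metrics["accuracy"]), 5 / 7)
  expect_equal(deg$counts$tp + deg$counts$fp, 0)  # classify none (majority neg)

  set.seed(202)
  for (rep in 1:25) {
    n <- sample(8:25, 1)
    scores <- sample(seq(0, 3, 0.5), n, replace = TRUE)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    dir <- sample(c("higher", "lower"), 1)
    got <- best_accuracy_operating_point(scores, labels, dir)
    expect_equal(unname(got$metrics["accuracy"]),
                 oracle_best_accuracy(scores, labels, dir))
    prev <- mean(labels)
    expect_gte(got$metrics["accuracy"], max(prev, 1 - prev))
    # returned threshold reproduces the returned counts
    pred <- if (dir == "lower") scores < got$threshold else scores > got$threshold
    expect_equal(got$counts$tp, sum(pred & labels))
    expect_equal(got$counts$tn, sum(!pred & !labels))
  }
})

test_that("specificity-constrained point maximizes sensitivity subject to the floor", {
  y <- c(rep(TRUE, 4), rep(FALSE, 4))
  sep <- spec_constrained_operating_point(c(5, 6, 7, 8, 1, 2, 3, 4), y)
  expect_equal(unname(sep$metrics["sensitivity"]), 1)
  expect_equal(unname(sep$metrics["specificity"]), 1)

  # anti-predictive scores: only the classify-none rule achieves the floor
  tight <- spec_constrained_operating_point(c(1, 2), c(TRUE, FALSE),
                                            min_specificity = 0.9)
  expect_equal(unname(tight$metrics["sensitivity"]), 0)
  expect_equal(unname(tight$metrics["specificity"]), 1)
  expect_error(spec_constrained_operating_point(c(1, 2), c(TRUE, FALSE),
                                                min_specificity = 2),
               "min_specificity")

  set.seed(303)
  for (rep in 1:25) {
    n <- sample(10:25, 1)
    scores <- sample(seq(0, 3, 0.25), n, replace = TRUE)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    got <- spec_constrained_operating_point(scores, labels, "higher", 0.9)
    expect_gte(got$metrics["specificity"], 0.9)
    # exhaustive scan oracle on sensitivity under the constraint
    best_sens <- 0
    for (t in sort(unique(c(scores - 1e-9, scores + 1e-9, -10, 10)))) {
      pred <- scores > t
      spec <- sum(!pred & !labels) / sum(!labels)
      if (spec >= 0.9)
        best_sens <- max(best_sens, sum(pred & labels) / sum(labels))
    }
    expect_equal(unname(got$metrics["sensitivity"]), best_sens)
  }
})

test_that("confusion metrics and exact binomial intervals behave as published tools", {
  m <- confusion_metrics(confusion_counts(12, 5, 1, 9))
  expect_equal(unname(round_half_up(m)), c(0.71, 0.90, 0.78))
  m <- confusion_metrics(confusion_counts(15, 2, 3, 7))
  expect_equal(unname(round_half_up(m)), c(0.88, 0.70, 0.81))
  expect_equal(unname(confusion_metrics(confusion_counts(5, 0, 0, 5))),
               c(1, 1, 1))
  expect_error(confusion_metrics(confusion_counts(0, 0, 1, 1)), "margin")

  # Clopper-Pearson vs stats::binom.test across a sweep
  for (n in c(1, 5, 10, 17, 27)) {
    for (s in 0:n) {
      ci <- clopper_pearson_ci(s, n)
      ref <- stats::binom.test(s, n)$conf.int
      expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-10)
      expect_true(ci["lower"] <= s / n + 1e-12 && ci["upper"] >= s / n - 1e-12)
    }
  }
  expect_equal(unname(clopper_pearson_ci(0, 10)["lower"]), 0)
  expect_equal(unname(clopper_pearson_ci(10, 10)["upper"]), 1)
  # interval widens as alpha shrinks
  wide <- clopper_pearson_ci(12, 17, alpha = 0.01)
  narrow <- clopper_pearson_ci(12, 17, alpha = 0.1)
  expect_lt(wide["lower"], narrow["lower"])
  expect_gt(wide["upper"], narrow["upper"])
  expect_error(clopper_pearson_ci(5, 4), "invalid")
})

test_that("exact McNemar reduces to the binomial tail on discordant pairs", {
  expect_equal(mcnemar_exact(3, 3)$p_value, 1)
  expect_equal(mcnemar_exact(0, 0)$p_value, 1)
  expect_equal(mcnemar_exact(0, 6)$p_value, 2 * (1 / 64))
  expect_equal(mcnemar_exact(2, 9)$p_value,
               min(1, 2 * stats::binom.test(2, 11)$p.value / 2), # one tail x2
               tolerance = 1e-12)
  expect_error(mcnemar_exact(-1, 2), "non-negative")

  # chi-square variant agrees with the textbook statistic
  cs <- mcnemar_exact(3, 9, method = "chisq")
  expect_equal(cs$statistic, 36 / 12)
  expect_equal(cs$p_value, pchisq(3, 1, lower.tail = FALSE))
  expect_equal(mcnemar_exact(0, 0, method = "chisq")$p_value, 1)
})

test_that("delong_test matches its structural-component definition and pROC", {
  set.seed(404)
  n <- 30
  labels <- c(rep(TRUE, 12), rep(FALSE, 18))
  a <- rnorm(n) + labels * 1.2
  b <- 0.6 * a + rnorm(n, sd = 0.8) + labels * 0.8

  self <- delong_test(a, a, labels)
  expect_equal(self$p_value, 1)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$auc_a, roc_auc(a, labels))

  dl <- delong_test(a, b, labels)
  # exhaustive-enumeration oracle for the one-curve DeLong variance
  x <- a[labels]; y <- a[!labels]
  v10 <- sapply(x, function(xx) mean((xx > y) + 0.5 * (xx == y)))
  v01 <- sapply(y, function(yy) mean((x > yy) + 0.5 * (x == yy)))
  var_a_oracle <- var(v10) / length(x) + var(v01) / length(y)
  expect_equal(dl$var_a, var_a_oracle, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  ra <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dl$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
  expect_equal(dl$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)

  expect_error(delong_test(c(1, 2, 3), c(1, 2), c(TRUE, FALSE, TRUE)),
               "paired")
})
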
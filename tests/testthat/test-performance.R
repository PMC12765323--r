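# closed-form Wilson oracle, written independently of the implementation
wilson_oracle <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  a <- (2 * n * p + z^2) / (2 * (n + z^2))
  b <- z * sqrt(z^2 + 4 * n * p * (1 - p)) / (2 * (n + z^2))
  c(max(0, a - b), min(1, a + b))
}

test_that("Wilson intervals reproduce the published per-gene intervals", {
  # (k, n, lower%, upper%) as printed to one decimal in the reference table
  cases <- rbind(c(217, 297, 67.7, 77.8),
                 c(22, 22, 85.1, 100.0),
                 c(1, 2, 9.5, 90.5),
                 c(1, 1, 20.7, 100.0),
                 c(34, 34, 89.8, 100.0))
  for (i in seq_len(nrow(cases))) {
    ci <- wilson_interval(cases[i, 1], cases[i, 2])
    expect_equal(floor(100 * ci$lower * 10 + 0.5) / 10, cases[i, 3],
                 tolerance = 1e-8)
    expect_equal(floor(100 * ci$upper * 10 + 0.5) / 10, cases[i, 4],
                 tolerance = 1e-8)
  }
})

test_that("Wilson interval equals the textbook closed form and contains k/n", {
  withr::with_seed(17, {
    for (i in 1:200) {
      n <- sample(1:500, 1)
      k <- sample(0:n, 1)
      ci <- wilson_interval(k, n)
      or <- wilson_oracle(k, n)
      expect_equal(c(ci$lower, ci$upper), or, tolerance = 1e-12)
      expect_true(ci$lower <= k / n + 1e-12 && k / n <= ci$upper + 1e-12)
    }
    # independent route: score-test interval from prop.test without correction
    pt <- prop.test(37, 120, correct = FALSE)$conf.int
    ci <- wilson_interval(37, 120)
    expect_equal(c(ci$lower, ci$upper), as.numeric(pt), tolerance = 1e-10)
  })
})

test_that("Wilson interval shrinks with n at fixed proportion and rejects n = 0", {
  widths <- sapply(c(10, 40, 160, 640), function(n) {
    ci <- wilson_interval(0.3 * n, n)
    ci$upper - ci$lower
  })
  expect_true(all(diff(widths) < 0))
  expect_error(wilson_interval(0, 0), class = "missbench_error_undefined")
})

test_that("cohort metrics under both ambiguous policies match hand formulas", {
  ct <- cohort_confusion()
  ex <- performance_metrics(ct, "exclude")
  expect_equal(ex$estimate[ex$metric == "sensitivity"], 1252 / 1577)
  expect_equal(ex$estimate[ex$metric == "specificity"], 2115 / 2248)
  expect_equal(ex$estimate[ex$metric == "fdr"], 133 / 1385)
  ae <- performance_metrics(ct, "as_error")
  expect_equal(ae$estimate[ae$metric == "sensitivity"], 1252 / 1796)
  expect_equal(ae$estimate[ae$metric == "specificity"], 2115 / 2408)
  expect_equal(ae$estimate[ae$metric == "fdr"], 293 / 1545)
  # excluding ambiguity never hurts: strict inequalities when ambig counts > 0
  expect_true(ex$estimate[1] > ae$estimate[1])
  expect_true(ex$estimate[2] > ae$estimate[2])
  expect_true(ex$estimate[3] < ae$estimate[3])
})

test_that("perfect tables give perfect metrics and zero denominators go undefined", {
  perfect <- confusion_table(tp = 5, fp = 0, tn = 5, fn = 0)
  for (pol in c("exclude", "as_error")) {
    pm <- performance_metrics(perfect, pol)
    expect_equal(pm$estimate, c(1, 1, 0))
  }
  onesided <- confusion_table(tp = 0, fp = 0, tn = 3, fn = 0)
  pm <- performance_metrics(onesided, "exclude")
  expect_true(is.na(pm$estimate[pm$metric == "sensitivity"]))
  expect_match(pm$note[pm$metric == "sensitivity"], "denominator")
  expect_equal(pm$estimate[pm$metric == "specificity"], 1)
})

test_that("panel summaries pool and average the reference per-gene counts", {
  tabs <- top20_confusion()
  ps <- panel_summary(tabs)
  expect_equal(ps$micro_fdr, 19 / 773)
  expect_equal(ps$macro_specificity, 0.933, tolerance = 5e-4)
  expect_equal(ps$genes_specificity, 19)  # one gene has tn + fp = 0
  # the two macro-sensitivity conventions
  expect_equal(panel_summary(tabs, "drop_zero_tp")$macro_sensitivity, 0.832,
               tolerance = 5e-4)
  # averaging in the tp = 0 gene pulls the macro mean down ~4 points
  expect_equal(ps$macro_sensitivity, 0.7906, tolerance = 1e-4)
  # single gene: macro equals that gene's values
  one <- tabs[tabs$scope == "RHO", ]
  expect_equal(panel_summary(one)$macro_sensitivity, 29 / 33)
})

test_that("per-gene report carries counts, intervals and one-sided notes", {
  rep <- per_gene_report(top20_confusion())
  abca4 <- rep[rep$gene == "ABCA4", ]
  expect_equal(abca4$sensitivity, 217 / 297)
  expect_equal(round(100 * abca4$spec_lower, 1), 85.1)
  expect_match(abca4$notes, "no false positives")
  prpf31 <- rep[rep$gene == "PRPF31", ]
  expect_true(is.na(prpf31$specificity))
  expect_match(prpf31$notes, "no false negatives")
})

# rank-free AUROC oracle: count concordant pathogenic x benign pairs
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == "pathogenic"]
  neg <- scores[labels == "benign"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUROC from midranks equals brute-force pair counting", {
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(10:120, 1)
      labels <- sample(c("pathogenic", "benign"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      # three-decimal grid to force ties
      scores <- round(runif(n), 3)
      r <- roc_pr(scores, labels)
      expect_equal(r$auroc, auroc_oracle(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("ROC/PR behave at the boundaries of separability", {
  sep <- roc_pr(c(0.9, 0.8, 0.85, 0.1, 0.2, 0.15),
                c(rep("pathogenic", 3), rep("benign", 3)))
  expect_equal(sep$auroc, 1)
  expect_equal(sep$auprc, 1)
  # labels independent of scores: AUROC near 1/2
  withr::with_seed(31, {
    n <- 4000
    r <- roc_pr(runif(n), sample(c("pathogenic", "benign"), n, replace = TRUE))
    expect_lt(abs(r$auroc - 0.5), 0.03)
    # AUPRC near the positive prevalence under independence
    expect_lt(abs(r$auprc - r$n_pos / n), 0.05)
  })
  expect_error(roc_pr(c(0.1, 0.9), c("benign", "benign")),
               class = "missbench_error_undefined")
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    labels <- sample(c("pathogenic", "benign"), 300, replace = TRUE)
    scores <- round(runif(300) + 0.3 * (labels == "pathogenic"), 3)
    scores <- pmin(pmax(scores, 0), 1)
    ours <- roc_pr(scores, labels)$auroc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(labels, levels = c("benign", "pathogenic")),
      predictor = scores, quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})
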
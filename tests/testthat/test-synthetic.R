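test_that("generation is deterministic given the seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 33, n_variants = 500, n_genes = 3)
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  for (f in c("predictor.tsv", "clinical.tsv", "population.tsv", "truth.tsv",
              "panel.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed diverges
  generate_cohort(synthetic_config(seed = 34, n_variants = 500, n_genes = 3), d2)
  expect_false(identical(readLines(file.path(d1, "predictor.tsv")),
                         readLines(file.path(d2, "predictor.tsv"))))
})

test_that("degenerate prevalence configurations behave as stated", {
  g0 <- generate_cohort(synthetic_config(seed = 2, n_variants = 300,
                                         p_truth_pathogenic = 0))
  expect_equal(sum(g0$truth$truth_class == "pathogenic"), 0)
  g1 <- generate_cohort(synthetic_config(seed = 2, n_variants = 300,
                                         p_truth_pathogenic = 1))
  expect_equal(sum(g1$truth$truth_class == "benign"), 0)
  expect_error(synthetic_config(p_truth_pathogenic = 1.4),
               class = "missbench_error_config")
  expect_error(synthetic_config(a_p = -1), class = "missbench_error_config")
})

test_that("generated protein changes are valid missense substitutions", {
  g <- generate_cohort(synthetic_config(seed = 8, n_variants = 400, n_genes = 4))
  parsed <- parse_protein_change(g$truth$protein_change)
  expect_false(anyNA(parsed$position))
  expect_true(all(parsed$ref_aa != parsed$alt_aa))
  expect_equal(anyDuplicated(g$truth$key), 0)
})

test_that("homozygote counts follow the Hardy-Weinberg expectation", {
  cfg <- synthetic_config(seed = 99, n_variants = 10000)
  g <- generate_cohort(cfg)
  # the AF model: mean log10 AF per class matches the truncated-normal mean
  # (computed by numerical integration, independent of the sampler)
  trunc_mean <- function(mu, sd) {
    lo <- stats::pnorm(-8, mu, sd); hi <- stats::pnorm(0, mu, sd)
    integrate(function(l) l * stats::dnorm(l, mu, sd) / (hi - lo),
              -8, 0, rel.tol = 1e-10)$value
  }
  for (cls in c("pathogenic", "benign")) {
    sub <- g$truth[g$truth$truth_class == cls, ]
    mu <- if (cls == "pathogenic") cfg$af_mu_p else cfg$af_mu_b
    sd_ <- if (cls == "pathogenic") cfg$af_sd_p else cfg$af_sd_b
    laf <- log10(sub$allele_frequency)
    expect_true(all(laf >= -8 & laf <= 0))
    se <- stats::sd(laf) / sqrt(nrow(sub))
    expect_lt(abs(mean(laf) - trunc_mean(mu, sd_)), 3 * se)
  }
  # the homozygote draw: conditionally on the drawn AFs, mean count matches
  # N * mean(AF^2) with the exact binomial standard error
  af2 <- g$truth$allele_frequency^2
  expected <- cfg$pop_size * mean(af2)
  se_cond <- sqrt(sum(cfg$pop_size * af2 * (1 - af2))) / length(af2)
  expect_lt(abs(mean(g$truth$homozygote_count) - expected), 3 * se_cond)
})

test_that("closed-form expectations hit the analytic extremes and symmetries", {
  # all pathogenic mass above 0.9, all benign mass below 0.1
  sharp <- synthetic_config(a_p = 400, b_p = 8, a_b = 8, b_b = 400)
  em <- expected_metrics(sharp)
  expect_equal(em$sensitivity, 1, tolerance = 1e-6)
  expect_equal(em$specificity, 1, tolerance = 1e-6)
  expect_equal(em$fdr, 0, tolerance = 1e-6)
  # mirror-imaged classes around symmetric thresholds: sens equals spec
  sym_cls <- classifier_config(benign_max = 0.4, pathogenic_min = 0.6)
  sym <- synthetic_config(a_p = 5, b_p = 2, a_b = 2, b_b = 5,
                          p_truth_pathogenic = 0.5,
                          p_labeled_pathogenic = 0.1, p_labeled_benign = 0.1)
  em2 <- expected_metrics(sym, sym_cls)
  expect_equal(em2$sensitivity, em2$specificity, tolerance = 1e-12)
})

test_that("label errors shift the closed-form expectations toward the other class", {
  clean <- expected_metrics(synthetic_config())
  noisy <- expected_metrics(synthetic_config(label_error_rate = 0.2))
  expect_lt(noisy$sensitivity, clean$sensitivity)
  expect_lt(noisy$specificity, clean$specificity)
  expect_gt(noisy$fdr, clean$fdr)
})

test_that("pipeline point estimates recover the closed form on a modest cohort", {
  cfg <- synthetic_config(seed = 404, n_variants = 20000,
                          p_labeled_pathogenic = 0.5, p_labeled_benign = 0.5)
  g <- generate_cohort(cfg)
  cohort <- g$truth[, c("key", "gene", "protein_change", "score",
                        "allele_frequency", "homozygote_count", "cadd_phred")]
  cohort$raw_label <- g$truth$label
  cohort$stars <- g$truth$stars
  cohort <- classify_cohort(cohort)
  cohort$confusion <- assign_confusion(cohort$predicted_class,
                                       cohort$clinical_status)
  pm <- performance_metrics(tabulate_confusion(cohort), "exclude")
  em <- expected_metrics(cfg)
  for (m in c("sensitivity", "specificity", "fdr")) {
    row <- pm[pm$metric == m, ]
    se <- sqrt(em[[m]] * (1 - em[[m]]) / row$n)
    expect_lt(abs(row$estimate - em[[m]]), 3 * se)
  }
})
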
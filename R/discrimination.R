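#' Welch two-sample t test (unequal variances)
#'
#' Computed from the closed formulas: `t = (mean_a - mean_b) /
#' sqrt(s2_a/n_a + s2_b/n_b)` with sample variances, Welch-Satterthwaite
#' degrees of freedom (not rounded), and a two-sided p-value from the t
#' distribution. Implemented directly so the zero-variance edge case can be
#' reported as a distinct undefined-statistic error rather than a generic
#' failure; agrees with `stats::t.test(var.equal = FALSE)` elsewhere.
#'
#' @param a,b Numeric vectors, each of length `>= 2`, finite.
#' @return Named numeric vector `c(t, df, p)`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stopf("missbench_error_undefined", "Welch t needs >= 2 values per group")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stopf("missbench_error_domain", "Welch t requires finite values")
  }
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    stopf("missbench_error_undefined",
          "zero variance in both groups: t statistic undefined")
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

#' Compare population metrics between concordant and discordant groups
#'
#' Runs the four Welch comparisons of the discrimination analysis:
#' log10 allele frequency and CADD phred, each between TP and FP variants and
#' between TN and FN variants. Allele frequency is log10-transformed before
#' testing (every cohort member has AF > 0 by construction); CADD is compared
#' on its native phred scale. Significance is flagged at the
#' Bonferroni-corrected threshold `alpha / n_comparisons` (0.05 / 4 =
#' 1.25e-2 at defaults). Comparisons with fewer than two members in either
#' group are reported as not computable rather than erroring.
#'
#' @param cohort Cohort tibble with `confusion`, `allele_frequency`,
#'   `cadd_phred` columns.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 4, the number of tests).
#' @return Tibble with one row per comparison: metric, groups, group sizes,
#'   means and SDs on the tested scale, natural-scale means for the allele
#'   frequency rows (`mean_a_natural`, `mean_b_natural`), `t`, `df`, `p`,
#'   `p_threshold`, `significant`, `computable`.
#' @export
compare_groups <- function(cohort, alpha = 0.05, n_comparisons = 4) {
  if (!("confusion" %in% names(cohort))) {
    stopf("missbench_error_domain", "cohort must carry confusion labels")
  }
  if (any(cohort$allele_frequency <= 0)) {
    stopf("missbench_error_domain",
          "allele frequencies must be positive for the log transform")
  }
  threshold <- alpha / n_comparisons

  pull <- function(group, metric) {
    v <- cohort[[metric]][cohort$confusion == group]
    if (metric == "allele_frequency") log10(v) else v
  }
  raw_mean <- function(group) {
    mean(cohort$allele_frequency[cohort$confusion == group])
  }

  plan <- list(
    list(metric = "log10_allele_frequency", src = "allele_frequency",
         a = "TP", b = "FP"),
    list(metric = "log10_allele_frequency", src = "allele_frequency",
         a = "TN", b = "FN"),
    list(metric = "cadd_phred", src = "cadd_phred", a = "TP", b = "FP"),
    list(metric = "cadd_phred", src = "cadd_phred", a = "TN", b = "FN")
  )
  rows <- lapply(plan, function(cmp) {
    va <- pull(cmp$a, cmp$src)
    vb <- pull(cmp$b, cmp$src)
    base <- tibble::tibble(
      metric = cmp$metric, group_a = cmp$a, group_b = cmp$b,
      n_a = length(va), n_b = length(vb),
      mean_a = if (length(va)) mean(va) else NA_real_,
      mean_b = if (length(vb)) mean(vb) else NA_real_,
      sd_a = if (length(va) > 1) sd(va) else NA_real_,
      sd_b = if (length(vb) > 1) sd(vb) else NA_real_,
      mean_a_natural = if (cmp$src == "allele_frequency" && length(va))
        raw_mean(cmp$a) else NA_real_,
      mean_b_natural = if (cmp$src == "allele_frequency" && length(vb))
        raw_mean(cmp$b) else NA_real_
    )
    if (length(va) < 2 || length(vb) < 2) {
      return(dplyr::mutate(base, t = NA_real_, df = NA_real_, p = NA_real_,
                           p_threshold = threshold, significant = NA,
                           computable = FALSE))
    }
    w <- welch_t(va, vb)
    dplyr::mutate(base, t = w[["t"]], df = w[["df"]], p = w[["p"]],
                  p_threshold = threshold,
                  significant = w[["p"]] < threshold, computable = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Homozygote rates per confusion group
#'
#' For each of TP, FP, TN and FN: the share of variants with at least one
#' reported homozygote, as a percent of the group.
#'
#' @param cohort Cohort tibble with `confusion` and `homozygote_count`.
#' @return Tibble with `group`, `n_with_homozygote`, `n_total`,
#'   `rate_percent` (`NA` for an empty group). Invariant under row order.
#' @export
homozygote_rates <- function(cohort) {
  rows <- lapply(c("TP", "FP", "TN", "FN"), function(g) {
    hz <- cohort$homozygote_count[cohort$confusion == g]
    n <- length(hz)
    k <- sum(hz >= 1)
    tibble::tibble(group = g, n_with_homozygote = k, n_total = n,
                   rate_percent = if (n > 0) 100 * k / n else NA_real_)
  })
  dplyr::bind_rows(rows)
}
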
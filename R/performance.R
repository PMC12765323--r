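#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval is centered at `(p + z^2/2n) / (1 + z^2/n)` with
#' half-width `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`; bounds are
#' clamped to `[0, 1]`. Unlike the Wald interval it behaves sensibly at
#' `k = 0` and `k = n`, which per-gene benchmarking hits constantly
#' (e.g. genes with no false positives).
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials (vectorized, all `>= 1`).
#' @param confidence Coverage level in (0, 1); default 0.95.
#' @return Tibble with columns `lower` and `upper`.
#' @examples
#' wilson_interval(22, 22)   # lower bound ~0.851
#' wilson_interval(1, 2)     # ~ (0.095, 0.905)
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (!(confidence > 0 && confidence < 1)) {
    stopf("missbench_error_config", "confidence must be in (0, 1)")
  }
  if (any(is.na(k)) || any(is.na(n)) || any(n < 1) || any(k < 0) || any(k > n)) {
    stopf("missbench_error_undefined",
          "Wilson interval requires 0 <= k <= n with n >= 1")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Sensitivity, specificity and FDR from a confusion table
#'
#' Computes the three benchmark proportions with Wilson intervals under one
#' of two ambiguous-handling policies. Under `"exclude"` (the primary
#' analysis) ambiguous predictions drop out of every denominator:
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, FDR `fp/(fp+tp)`.
#' Under `"as_error"` (the sensitivity analysis) ambiguous predictions on
#' pathogenic variants count as false negatives and those on benign variants
#' as false positives before the same formulas are applied. A metric whose
#' denominator is zero is reported as undefined (`NA` with a reason), never
#' as a silent `NaN`.
#'
#' @param table One-row confusion tibble (see [confusion_table()]).
#' @param policy `"exclude"` or `"as_error"`.
#' @param confidence Wilson interval coverage.
#' @return Tibble with one row per metric: `scope`, `policy`, `metric`, `k`,
#'   `n`, `estimate`, `lower`, `upper`, `note`.
#' @export
performance_metrics <- function(table, policy = c("exclude", "as_error"),
                                confidence = 0.95) {
  policy <- match.arg(policy)
  stopifnot(nrow(table) == 1)
  tp <- table$tp; tn <- table$tn
  fn <- table$fn + if (policy == "as_error") table$ambig_p else 0
  fp <- table$fp + if (policy == "as_error") table$ambig_b else 0

  one <- function(metric, k, n) {
    if (n == 0) {
      return(tibble::tibble(scope = table$scope, policy = policy,
                            metric = metric, k = k, n = n,
                            estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_, note = "undefined: denominator 0"))
    }
    ci <- wilson_interval(k, n, confidence)
    tibble::tibble(scope = table$scope, policy = policy, metric = metric,
                   k = k, n = n, estimate = k / n,
                   lower = ci$lower, upper = ci$upper, note = NA_character_)
  }
  dplyr::bind_rows(one("sensitivity", tp, tp + fn),
                   one("specificity", tn, tn + fp),
                   one("fdr", fp, fp + tp))
}

#' Per-gene performance report
#'
#' One row per gene with counts, sensitivity and specificity point estimates
#' plus Wilson bounds (exclude policy), and a notes column flagging one-sided
#' tables (no false positives / no false negatives observed).
#'
#' @param tables Confusion tibble from `tabulate_confusion(by_gene = TRUE)`
#'   (the `"cohort"` row is dropped if present).
#' @param confidence Wilson interval coverage.
#' @return Tibble with columns `gene`, `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `sens_lower`, `sens_upper`, `specificity`, `spec_lower`,
#'   `spec_upper`, `notes`.
#' @export
per_gene_report <- function(tables, confidence = 0.95) {
  genes <- tables[tables$scope != "cohort", , drop = FALSE]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    pm <- performance_metrics(g, "exclude", confidence)
    sens <- pm[pm$metric == "sensitivity", ]
    spc <- pm[pm$metric == "specificity", ]
    notes <- c(
      if (g$fp == 0 && g$tn > 0) "no false positives observed",
      if (g$fn == 0 && g$tp > 0) "no false negatives observed"
    )
    tibble::tibble(gene = g$scope, tp = g$tp, fn = g$fn, tn = g$tn, fp = g$fp,
                   sensitivity = sens$estimate, sens_lower = sens$lower,
                   sens_upper = sens$upper, specificity = spc$estimate,
                   spec_lower = spc$lower, spec_upper = spc$upper,
                   notes = paste(notes, collapse = "; "))
  })
  dplyr::bind_rows(rows)
}

#' Panel-level macro and micro summaries
#'
#' Macro averages take the unweighted mean of defined per-gene metrics; the
#' micro FDR pools counts across genes first (`sum(fp) / (sum(fp) + sum(tp))`).
#' Published panel summaries are ambiguous about genes with zero true
#' positives (sensitivity defined but 0), so the macro sensitivity rule is
#' selectable: `"defined"` averages every gene with `tp + fn > 0`;
#' `"drop_zero_tp"` additionally drops genes with `tp = 0`.
#'
#' @param tables Per-gene confusion tibble (the `"cohort"` row is dropped).
#' @param macro_rule Macro-sensitivity convention, see above.
#' @return List: `macro_sensitivity`, `macro_specificity`, `micro_fdr`,
#'   `genes_sensitivity`, `genes_specificity`, `n_genes`.
#' @export
panel_summary <- function(tables, macro_rule = c("defined", "drop_zero_tp")) {
  macro_rule <- match.arg(macro_rule)
  g <- tables[tables$scope != "cohort", , drop = FALSE]
  if (nrow(g) == 0) {
    stopf("missbench_error_undefined", "panel summary needs >= 1 gene table")
  }
  sens_def <- g$tp + g$fn > 0
  if (macro_rule == "drop_zero_tp") sens_def <- sens_def & g$tp > 0
  spec_def <- g$tn + g$fp > 0
  list(
    macro_sensitivity = mean((g$tp / (g$tp + g$fn))[sens_def]),
    macro_specificity = mean((g$tn / (g$tn + g$fp))[spec_def]),
    micro_fdr = sum(g$fp) / (sum(g$fp) + sum(g$tp)),
    genes_sensitivity = sum(sens_def),
    genes_specificity = sum(spec_def),
    n_genes = nrow(g)
  )
}

#' Continuous-score discrimination: AUROC and AUPRC
#'
#' Treats the clinically pathogenic class as positive and evaluates the raw
#' score as a continuous classifier, restricted to variants explicitly
#' labeled pathogenic or benign. AUROC is computed from the midrank
#' (Mann-Whitney) statistic, which equals the trapezoidal ROC area and
#' handles the heavy score ties of three-decimal grids correctly. AUPRC is
#' the stepwise precision-recall summation over distinct score thresholds
#' (average precision).
#'
#' @param scores Numeric score vector.
#' @param labels Collapsed clinical labels (`pathogenic` / `benign`; other
#'   values are dropped).
#' @return List with `auroc`, `auprc`, `n_pos`, `n_neg`.
#' @export
roc_pr <- function(scores, labels) {
  labels <- as.character(labels)
  keep <- labels %in% c("pathogenic", "benign")
  scores <- scores[keep]
  labels <- labels[keep]
  pos <- labels == "pathogenic"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stopf("missbench_error_undefined",
          "ROC/PR need at least one pathogenic and one benign label")
  }
  r <- rank(scores)  # midranks for ties
  auroc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  y <- pos[ord]
  s <- scores[ord]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(!y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)  # threshold boundaries
  tp <- cum_tp[last_of_tie]
  fp <- cum_fp[last_of_tie]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  drecall <- diff(c(0, recall))
  auprc <- sum(precision * drecall)

  list(auroc = auroc, auprc = auprc, n_pos = n1, n_neg = n0)
}
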
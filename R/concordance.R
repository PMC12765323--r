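CONFUSION_LEVELS <- c("TP", "FP", "TN", "FN", "AMBIG_P", "AMBIG_B",
                      "NOT_EVALUABLE")

#' Assign a confusion label to each prediction/annotation pair
#'
#' The full 3x2 mapping between the predicted class and the collapsed
#' clinical label: pathogenic predictions on clinically pathogenic variants
#' are TP, benign predictions on pathogenic variants FN, pathogenic on benign
#' FP, benign on benign TN; ambiguous predictions get their own labels
#' (`AMBIG_P` on pathogenic, `AMBIG_B` on benign) so the two
#' ambiguous-handling policies can be applied downstream. Variants without a
#' definitive clinical label (ineligible or absent) are `NOT_EVALUABLE`.
#'
#' @param predicted Factor/character of predicted classes
#'   (`benign`/`ambiguous`/`pathogenic`).
#' @param clinical Factor/character of collapsed clinical statuses
#'   (`pathogenic`/`benign`/`ineligible`/`absent`).
#' @return Factor with levels `TP`, `FP`, `TN`, `FN`, `AMBIG_P`, `AMBIG_B`,
#'   `NOT_EVALUABLE`.
#' @export
assign_confusion <- function(predicted, clinical) {
  predicted <- as.character(predicted)
  clinical <- as.character(clinical)
  n <- max(length(predicted), length(clinical))
  predicted <- rep_len(predicted, n)
  clinical <- rep_len(clinical, n)
  out <- rep("NOT_EVALUABLE", n)
  path <- !is.na(clinical) & clinical == "pathogenic"
  ben <- !is.na(clinical) & clinical == "benign"
  out[path & predicted == "pathogenic"] <- "TP"
  out[path & predicted == "benign"] <- "FN"
  out[path & predicted == "ambiguous"] <- "AMBIG_P"
  out[ben & predicted == "benign"] <- "TN"
  out[ben & predicted == "pathogenic"] <- "FP"
  out[ben & predicted == "ambiguous"] <- "AMBIG_B"
  factor(out, levels = CONFUSION_LEVELS)
}

#' Construct a confusion table row from counts
#'
#' Convenience constructor used for published count tables and tests.
#'
#' @param tp,fp,tn,fn,ambig_p,ambig_b Non-negative counts.
#' @param scope `"cohort"` or a gene symbol.
#' @return One-row tibble with the standard confusion columns.
#' @export
confusion_table <- function(tp, fp, tn, fn, ambig_p = 0, ambig_b = 0,
                            scope = "cohort") {
  counts <- c(tp, fp, tn, fn, ambig_p, ambig_b)
  if (any(is.na(counts)) || any(counts < 0)) {
    stopf("missbench_error_domain", "confusion counts must be non-negative")
  }
  tibble::tibble(scope = scope, tp = tp, fp = fp, tn = tn, fn = fn,
                 ambig_p = ambig_p, ambig_b = ambig_b)
}

#' Tabulate confusion counts at cohort and per-gene scope
#'
#' @param cohort Classified cohort with a `confusion` column (added here from
#'   `predicted_class`/`clinical_status` if missing).
#' @param by_gene If `TRUE`, append one row per gene with at least one
#'   evaluable member; per-gene counts always sum to the cohort row.
#' @return Tibble of confusion rows (see [confusion_table()]); zero rows for
#'   an empty cohort.
#' @export
tabulate_confusion <- function(cohort, by_gene = FALSE) {
  if (nrow(cohort) == 0) return(confusion_table(1, 0, 0, 0)[0, ])
  if (!("confusion" %in% names(cohort))) {
    cohort$confusion <- assign_confusion(cohort$predicted_class,
                                         cohort$clinical_status)
  }
  count_scope <- function(df, scope) {
    cc <- table(df$confusion)
    confusion_table(tp = unname(cc["TP"]), fp = unname(cc["FP"]),
                    tn = unname(cc["TN"]), fn = unname(cc["FN"]),
                    ambig_p = unname(cc["AMBIG_P"]),
                    ambig_b = unname(cc["AMBIG_B"]), scope = scope)
  }
  out <- count_scope(cohort, "cohort")
  if (by_gene) {
    evaluable <- cohort[cohort$confusion != "NOT_EVALUABLE", , drop = FALSE]
    for (g in sort(unique(evaluable$gene))) {
      out <- dplyr::bind_rows(
        out, count_scope(cohort[cohort$gene == g, , drop = FALSE], g))
    }
  }
  out
}

#' @rdname tabulate_confusion
#' @param tables Confusion tibble from [tabulate_confusion()].
#' @param path Output TSV path.
#' @export
write_confusion <- function(tables, path) {
  readr::write_tsv(tables, path, progress = FALSE)
  invisible(path)
}
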
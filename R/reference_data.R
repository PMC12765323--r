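#' Bundled reference tables
#'
#' Small plain-text reference tables shipped with the package, used by the
#' worked examples, the analysis scripts and the test suite:
#'
#' * `ird_top20_confusion.tsv` — per-gene confusion counts (TP/FN/TN/FP) for
#'   the 20 most commonly implicated inherited-retinal-disease genes from a
#'   published AlphaMissense-vs-ClinVar benchmark.
#' * `ird_cohort_confusion.tsv` — the corresponding cohort-level confusion
#'   counts including ambiguous-range predictions.
#' * `ird_class_totals.tsv` — benign/ambiguous/pathogenic score-class counts
#'   over the full 128,248-variant population cohort.
#' * `abca4_hypomorphs.tsv` — score and population metrics for nine
#'   well-characterized hypomorphic ABCA4 variants.
#' * `abca4_query_pro1948leu.tsv` — population metrics for the ABCA4
#'   Pro1948Leu query variant used in the hypomorph-profile example.
#'
#' @param name File name of the bundled table.
#' @return `reference_path()` returns the installed file path;
#'   `read_reference()` returns the table as a tibble.
#' @examples
#' read_reference("abca4_hypomorphs.tsv")
#' @export
reference_path <- function(name) {
  p <- system.file("extdata", name, package = "missbench")
  if (!nzchar(p)) {
    stopf("missbench_error_config", "no bundled reference table '%s'", name)
  }
  p
}

#' @rdname reference_path
#' @export
read_reference <- function(name) {
  readr::read_tsv(reference_path(name), show_col_types = FALSE,
                  progress = FALSE)
}
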
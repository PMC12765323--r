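#' Assemble a benchmark run configuration
#'
#' Bundles every tunable of the pipeline with its default. `overrides` is the
#' reconciliation map passed through to [match_records()].
#'
#' @param classifier A [classifier_config()].
#' @param min_stars Review-star floor for clinical eligibility.
#' @param confidence Wilson interval coverage.
#' @param alpha,n_comparisons Discrimination significance settings.
#' @param thresholds A [flag_thresholds()].
#' @param overrides Optional named character vector of key overrides.
#' @param macro_rule Macro-sensitivity convention for [panel_summary()].
#' @return List of class `missbench_run_config`.
#' @export
benchmark_config <- function(classifier = classifier_config(),
                             min_stars = 1, confidence = 0.95,
                             alpha = 0.05, n_comparisons = 4,
                             thresholds = flag_thresholds(),
                             overrides = NULL,
                             macro_rule = "defined") {
  structure(list(classifier = classifier, min_stars = min_stars,
                 confidence = confidence, alpha = alpha,
                 n_comparisons = n_comparisons, thresholds = thresholds,
                 overrides = overrides, macro_rule = macro_rule),
            class = "missbench_run_config")
}

#' Read a benchmark configuration from YAML
#'
#' Recognized keys (all optional, defaults from [benchmark_config()]):
#' `classifier.benign_max`, `classifier.pathogenic_min`,
#' `clinical.min_stars`, `metrics.confidence`, `metrics.macro_rule`,
#' `discrimination.alpha`, `discrimination.n_comparisons`, `flagger.*`
#' (threshold fields), and `overrides` (mapping of clinical to predictor
#' keys).
#'
#' @param path YAML file path.
#' @return A [benchmark_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- y$classifier %||% list()
  fl <- y$flagger %||% list()
  ov <- y$overrides
  benchmark_config(
    classifier = classifier_config(
      benign_max = cl$benign_max %||% 0.34,
      pathogenic_min = cl$pathogenic_min %||% 0.564),
    min_stars = (y$clinical %||% list())$min_stars %||% 1,
    confidence = (y$metrics %||% list())$confidence %||% 0.95,
    alpha = (y$discrimination %||% list())$alpha %||% 0.05,
    n_comparisons = (y$discrimination %||% list())$n_comparisons %||% 4,
    thresholds = flag_thresholds(
      af_low_max = fl$af_low_max %||% 1e-4,
      af_high_min = fl$af_high_min %||% 1e-3,
      cadd_high_min = fl$cadd_high_min %||% 20,
      cadd_low_max = fl$cadd_low_max %||% 15,
      max_homozygotes_for_fn = fl$max_homozygotes_for_fn %||% 0),
    overrides = if (length(ov)) unlist(ov) else NULL,
    macro_rule = (y$metrics %||% list())$macro_rule %||% "defined"
  )
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full benchmarking pipeline
#'
#' Executes ingest, classification, concordance, performance (both
#' ambiguous-handling policies), discrimination and flagging, writing the
#' full report bundle to `out_dir`: `cohort.tsv`, `confusion.tsv` (cohort +
#' per-gene), `per_gene_report.tsv`, `discrimination.tsv`,
#' `homozygote_rates.tsv`, `flags.tsv` and `summary.json`. Counts at every
#' filtering step (panel restriction, population join, clinical eligibility,
#' ambiguous exclusion) are logged and duplicated into the summary JSON so
#' the filtering funnel is auditable.
#'
#' @param predictor_path,clinical_path,population_path Input TSV paths.
#' @param panel_path Optional plain-text gene list (one symbol per line).
#' @param out_dir Output directory, created if needed.
#' @param config A [benchmark_config()].
#' @return Invisibly, a list: `status` (`"ok"` or `"no_evaluable"`),
#'   `cohort`, `confusion`, `metrics`, `per_gene`, `panel`,
#'   `discrimination`, `rates`, `flags`, `roc`, `funnel`, `paths`.
#' @export
run_benchmark <- function(predictor_path, clinical_path, population_path,
                          panel_path = NULL, out_dir,
                          config = benchmark_config()) {
  panel <- if (!is.null(panel_path)) {
    trimws(readLines(panel_path, warn = FALSE))
  } else NULL

  predictor <- read_predictor_table(predictor_path, panel = panel)
  log_stage("ingest", "predictor: %d rows read, %d in panel",
            attr(predictor, "n_read"), nrow(predictor))
  clinical <- read_clinical_table(clinical_path)
  population <- read_population_table(population_path)
  log_stage("ingest", "clinical: %d records; population: %d records",
            nrow(clinical), nrow(population))

  asm <- assemble_cohort(predictor, clinical, population,
                         overrides = config$overrides)
  cohort <- classify_cohort(asm$cohort, config$classifier, config$min_stars)
  cohort$confusion <- assign_confusion(cohort$predicted_class,
                                       cohort$clinical_status)
  log_stage("cohort", "%d variants with population data (%d dropped); %d clinically definitive",
            nrow(cohort), asm$report$n_predictor_without_population,
            sum(cohort$confusion != "NOT_EVALUABLE"))

  confusion <- tabulate_confusion(cohort, by_gene = TRUE)
  cohort_tbl <- confusion[confusion$scope == "cohort", ]
  n_definitive <- sum(cohort_tbl$tp, cohort_tbl$fp, cohort_tbl$tn,
                      cohort_tbl$fn, cohort_tbl$ambig_p, cohort_tbl$ambig_b)
  n_ambiguous <- cohort_tbl$ambig_p + cohort_tbl$ambig_b
  log_stage("concordance", "%d evaluable, %d ambiguous-range excluded under primary policy",
            n_definitive, n_ambiguous)

  status <- if (n_definitive == 0) "no_evaluable" else "ok"
  metrics <- dplyr::bind_rows(
    performance_metrics(cohort_tbl, "exclude", config$confidence),
    performance_metrics(cohort_tbl, "as_error", config$confidence))
  per_gene <- per_gene_report(confusion, config$confidence)
  panel_sum <- if (nrow(per_gene) > 0) {
    panel_summary(confusion, config$macro_rule)
  } else NULL

  roc <- tryCatch(
    roc_pr(cohort$score, cohort$clinical_status),
    missbench_error_undefined = function(e) NULL)

  discrimination <- compare_groups(cohort, config$alpha, config$n_comparisons)
  rates <- homozygote_rates(cohort)
  flagged <- suspect_misclassification(cohort, config$thresholds)
  flags <- flagged[flagged$flag_kind != "NONE",
                   c("key", "flag_kind", "flag_reasons")]
  log_stage("flagger", "%d variant(s) flagged", nrow(flags))

  funnel <- list(
    n_predictor_read = attr(predictor, "n_read"),
    n_predictor_in_panel = asm$report$n_predictor,
    n_with_population = asm$report$n_cohort,
    n_without_population = asm$report$n_predictor_without_population,
    n_clinical_offered = asm$report$n_clinical_offered,
    n_clinical_matched = asm$report$clinical_match$matched,
    n_definitive = n_definitive,
    n_ambiguous_excluded = n_ambiguous,
    n_evaluable_after_exclusion = n_definitive - n_ambiguous
  )

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(out_dir, "cohort.tsv"),
    confusion = file.path(out_dir, "confusion.tsv"),
    per_gene = file.path(out_dir, "per_gene_report.tsv"),
    discrimination = file.path(out_dir, "discrimination.tsv"),
    rates = file.path(out_dir, "homozygote_rates.tsv"),
    flags = file.path(out_dir, "flags.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  write_cohort(cohort, paths$cohort)
  write_confusion(confusion, paths$confusion)
  readr::write_tsv(per_gene, paths$per_gene, progress = FALSE)
  readr::write_tsv(discrimination, paths$discrimination, progress = FALSE)
  readr::write_tsv(rates, paths$rates, progress = FALSE)
  readr::write_tsv(flags, paths$flags, progress = FALSE)

  summary <- list(
    status = status,
    funnel = funnel,
    metrics = metrics,
    panel = panel_sum,
    roc = roc,
    homozygote_rates = rates,
    n_flags = nrow(flags)
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(status = status, cohort = cohort, confusion = confusion,
                 metrics = metrics, per_gene = per_gene, panel = panel_sum,
                 discrimination = discrimination, rates = rates,
                 flags = flags, roc = roc, funnel = funnel, paths = paths))
}
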
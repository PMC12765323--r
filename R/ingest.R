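#' @importFrom dplyr inner_join left_join anti_join distinct group_by summarise
#'   mutate filter arrange bind_rows n across all_of
NULL

default_col_maps <- function() {
  list(
    predictor = c(gene = "gene", protein_change = "protein_variant",
                  score = "am_pathogenicity"),
    clinical = c(gene = "gene", protein_change = "protein_change",
                 raw_label = "clinical_significance", stars = "review_stars"),
    population = c(gene = "gene", protein_change = "protein_change",
                   allele_frequency = "allele_frequency",
                   homozygote_count = "homozygote_count",
                   cadd_phred = "cadd_phred")
  )
}

read_table_checked <- function(path, col_map, table_name) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(unname(col_map), names(df))
  if (length(missing) > 0) {
    stopf("missbench_error_schema",
          "%s table %s is missing required column(s): %s",
          table_name, path, paste(missing, collapse = ", "))
  }
  out <- df[, unname(col_map), drop = FALSE]
  names(out) <- names(col_map)
  tibble::as_tibble(out)
}

# normalize numeric dialects: thousands separators, stray whitespace
as_num <- function(x) {
  if (is.character(x)) x <- gsub("[, ]", "", x)
  suppressWarnings(as.numeric(x))
}

# parse keys leniently, dropping malformed rows with a message; keeps line
# numbers (1-based data rows) for auditability
drop_malformed <- function(df, table_name) {
  if (nrow(df) == 0) {
    df$key <- character(0)
    return(df)
  }
  parsed <- parse_protein_change(df$protein_change, strict = FALSE)
  bad <- which(!parsed$ok)
  if (length(bad) > 0) {
    message(sprintf("[%s] skipped %d row(s) with unusable protein changes (rows: %s)",
                    table_name, length(bad),
                    paste(utils::head(bad, 10), collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
    parsed <- parsed[-bad, , drop = FALSE]
  }
  df$key <- paste0(toupper(trimws(df$gene)), ":", format_protein_change(parsed))
  df$gene <- toupper(trimws(df$gene))
  df$protein_change <- format_protein_change(parsed)
  df
}

dedupe_keys <- function(df, table_name) {
  dup <- duplicated(df$key)
  if (any(dup)) {
    warn(sprintf("[%s] %d duplicate key(s); keeping the first record of each",
                 table_name, sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Read a predictor score table
#'
#' Reads an AlphaMissense-style TSV of precomputed missense pathogenicity
#' scores, restricts it to a gene panel, validates scores, and normalizes
#' protein changes into join keys. `#`-prefixed header lines are tolerated.
#'
#' @param path Path to a TSV with (at least) gene, protein change and score
#'   columns.
#' @param panel Optional character vector of panel gene symbols; rows outside
#'   the panel are dropped. `NULL` keeps every gene.
#' @param col_map Named character vector mapping the internal names `gene`,
#'   `protein_change`, `score` to the file's column names.
#' @param transcript_map Optional named character vector (gene -> canonical
#'   transcript). When the file has a `transcript` column, records from other
#'   transcripts of mapped genes are dropped before deduplication.
#' @return Tibble with `key`, `gene`, `protein_change`, `score` (plus
#'   `transcript` when present). Attribute `n_read` records the row count
#'   before panel filtering.
#' @export
read_predictor_table <- function(path, panel = NULL,
                                 col_map = default_col_maps()$predictor,
                                 transcript_map = NULL) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  df <- read_table_checked(path, col_map, "predictor")
  if ("transcript" %in% names(raw)) df$transcript <- raw$transcript
  n_read <- nrow(df)

  if (!is.null(panel)) {
    df <- df[toupper(trimws(df$gene)) %in% toupper(trimws(panel)), , drop = FALSE]
  }
  df$score <- as_num(df$score)
  bad <- which(is.na(df$score) | df$score < 0 | df$score > 1)
  if (length(bad) > 0) {
    stopf("missbench_error_row",
          "predictor table %s: score outside [0, 1] or missing at data row(s) %s",
          path, paste(utils::head(bad, 10), collapse = ", "))
  }
  df <- drop_malformed(df, "predictor")
  if (!is.null(transcript_map) && "transcript" %in% names(df)) {
    mapped <- df$gene %in% names(transcript_map)
    keep <- !mapped | df$transcript == unname(transcript_map[df$gene])
    df <- df[keep, , drop = FALSE]
  }
  df <- dedupe_keys(df, "predictor")
  out <- df[, c("key", "gene", "protein_change", "score",
                intersect("transcript", names(df)))]
  attr(out, "n_read") <- n_read
  out
}

#' Read a clinical annotation table
#'
#' Reads a ClinVar-style TSV of clinical significance assertions. Raw labels
#' are preserved verbatim for auditing; collapsing to pathogenic/benign
#' happens later in [collapse_clinical()]. Rows with unusable protein changes
#' are skipped with a message.
#'
#' @param path Path to the TSV.
#' @param col_map Named character vector mapping `gene`, `protein_change`,
#'   `raw_label`, `stars` to the file's column names.
#' @return Tibble with `key`, `gene`, `protein_change`, `raw_label`, `stars`.
#' @export
read_clinical_table <- function(path, col_map = default_col_maps()$clinical) {
  df <- read_table_checked(path, col_map, "clinical")
  df$stars <- as_num(df$stars)
  bad <- which(is.na(df$stars) | df$stars %% 1 != 0 | df$stars < 0 | df$stars > 4)
  if (length(bad) > 0) {
    stopf("missbench_error_row",
          "clinical table %s: review stars must be integers 0-4 (data row(s) %s)",
          path, paste(utils::head(bad, 10), collapse = ", "))
  }
  df$stars <- as.integer(df$stars)
  df <- drop_malformed(df, "clinical")
  df <- dedupe_keys(df, "clinical")
  df[, c("key", "gene", "protein_change", "raw_label", "stars")]
}

#' Read a population metrics table
#'
#' Reads a gnomAD/CADD-style TSV of allele frequency, homozygote count and
#' phred-scaled CADD score per variant. Scientific notation and
#' thousands-separated counts are normalized at read time.
#'
#' @param path Path to the TSV.
#' @param col_map Named character vector mapping `gene`, `protein_change`,
#'   `allele_frequency`, `homozygote_count`, `cadd_phred` to the file's
#'   column names.
#' @return Tibble with `key`, `gene`, `protein_change`, `allele_frequency`,
#'   `homozygote_count`, `cadd_phred`.
#' @export
read_population_table <- function(path, col_map = default_col_maps()$population) {
  df <- read_table_checked(path, col_map, "population")
  df$allele_frequency <- as_num(df$allele_frequency)
  df$homozygote_count <- as_num(df$homozygote_count)
  df$cadd_phred <- as_num(df$cadd_phred)
  bad <- which(is.na(df$allele_frequency) | df$allele_frequency < 0 |
                 df$allele_frequency > 1 |
                 is.na(df$homozygote_count) | df$homozygote_count < 0 |
                 df$homozygote_count %% 1 != 0 |
                 is.na(df$cadd_phred) | df$cadd_phred < 0)
  if (length(bad) > 0) {
    stopf("missbench_error_row",
          "population table %s: invalid metric value(s) at data row(s) %s",
          path, paste(utils::head(bad, 10), collapse = ", "))
  }
  df$homozygote_count <- as.integer(df$homozygote_count)
  df <- drop_malformed(df, "population")
  df <- dedupe_keys(df, "population")
  df[, c("key", "gene", "protein_change", "allele_frequency",
         "homozygote_count", "cadd_phred")]
}

#' Assemble the analysis cohort
#'
#' The cohort is the inner join of the predictor and population tables on the
#' protein-level key — i.e. only variants with population (gnomAD-style) data
#' enter the analysis, so every member has a positive allele frequency.
#' Clinical annotations are attached where the key matches (optionally through
#' a reconciliation override map); members with no clinical record carry an
#' `NA` label, later classified as status `absent`.
#'
#' @param predictor,clinical,population Tibbles from the respective readers.
#' @param overrides Optional named character vector (clinical key ->
#'   predictor key) for reconciling annotation discrepancies.
#' @return A list with `cohort` (one row per variant: key, gene,
#'   protein_change, score, allele_frequency, homozygote_count, cadd_phred,
#'   raw_label, stars) and `report` (funnel counts plus the clinical
#'   [match_records()] report).
#' @export
assemble_cohort <- function(predictor, clinical, population, overrides = NULL) {
  pop <- population[, c("key", "allele_frequency", "homozygote_count",
                        "cadd_phred")]
  cohort <- dplyr::inner_join(predictor, pop, by = "key")
  if (nrow(cohort) == 0) {
    stopf("missbench_error_empty_cohort",
          "no predictor variants have population data: empty cohort")
  }
  if (any(cohort$allele_frequency <= 0)) {
    stopf("missbench_error_row",
          "cohort members must have positive allele frequency (population presence)")
  }

  m <- match_records(cohort$key, clinical$key, overrides)
  clin <- clinical[, c("key", "raw_label", "stars")]
  clin <- dplyr::inner_join(m$matched, clin,
                            by = c(clinical_key = "key"))[, c("predictor_key",
                                                              "raw_label",
                                                              "stars")]
  names(clin)[1] <- "key"
  cohort <- dplyr::left_join(cohort, clin, by = "key")

  report <- list(
    n_predictor = nrow(predictor),
    n_population = nrow(population),
    n_cohort = nrow(cohort),
    n_predictor_without_population = nrow(predictor) - nrow(cohort),
    n_clinical_offered = nrow(clinical),
    clinical_match = m$report
  )
  list(cohort = cohort, report = report)
}

#' Write / re-read a cohort table
#'
#' Cohort TSVs round-trip: re-reading a written cohort reproduces it.
#'
#' @param cohort Cohort tibble (optionally with `predicted_class`,
#'   `clinical_status`, `confusion` columns).
#' @param path Output TSV path.
#' @return `path` (write) or the cohort tibble (read).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("predicted_class" %in% names(df)) {
    df$predicted_class <- factor(df$predicted_class, levels = PREDICTED_LEVELS)
  }
  if ("clinical_status" %in% names(df)) {
    df$clinical_status <- factor(df$clinical_status, levels = CLINICAL_LEVELS)
  }
  if ("confusion" %in% names(df)) {
    df$confusion <- factor(df$confusion, levels = CONFUSION_LEVELS)
  }
  if ("stars" %in% names(df)) df$stars <- as.integer(df$stars)
  if ("homozygote_count" %in% names(df)) {
    df$homozygote_count <- as.integer(df$homozygote_count)
  }
  tibble::as_tibble(df)
}
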
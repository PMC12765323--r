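#' Classifier thresholds for the three-way score classification
#'
#' Scores below `benign_max` are called benign, scores above `pathogenic_min`
#' pathogenic, and everything in between ambiguous. The defaults are the
#' predictor's published high-precision cutoffs, stated there as the
#' three-decimal bands 0.000–0.333 / 0.334–0.564 / 0.565–1.000; the continuous
#' rule `benign <=> s < 0.34`, `pathogenic <=> s > 0.564` reproduces every
#' published three-decimal assignment while leaving no gap in (0.333, 0.334).
#'
#' @param benign_max Exclusive upper bound of the benign band (default 0.34).
#' @param pathogenic_min Exclusive lower bound of the pathogenic band
#'   (default 0.564).
#' @return A validated list of class `missbench_classifier_config`.
#' @export
classifier_config <- function(benign_max = 0.34, pathogenic_min = 0.564) {
  if (!(benign_max > 0 && benign_max <= pathogenic_min && pathogenic_min < 1)) {
    stopf("missbench_error_config",
          "require 0 < benign_max <= pathogenic_min < 1 (got %g, %g)",
          benign_max, pathogenic_min)
  }
  structure(list(benign_max = benign_max, pathogenic_min = pathogenic_min),
            class = "missbench_classifier_config")
}

PREDICTED_LEVELS <- c("benign", "ambiguous", "pathogenic")
CLINICAL_LEVELS <- c("pathogenic", "benign", "ineligible", "absent")

#' Classify pathogenicity scores into benign / ambiguous / pathogenic
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @param cfg A [classifier_config()].
#' @return Factor with levels `benign`, `ambiguous`, `pathogenic`. The rule is
#'   monotone in the score and the three classes partition `[0, 1]`.
#' @examples
#' classify_score(c(0.326, 0.343, 0.853))
#' @export
classify_score <- function(score, cfg = classifier_config()) {
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    stopf("missbench_error_domain", "scores must lie in [0, 1]")
  }
  out <- ifelse(score < cfg$benign_max, "benign",
                ifelse(score > cfg$pathogenic_min, "pathogenic", "ambiguous"))
  factor(out, levels = PREDICTED_LEVELS)
}

#' Collapse clinical significance labels into pathogenic / benign / ineligible
#'
#' `Pathogenic` and `Likely pathogenic` collapse to pathogenic; `Benign` and
#' `Likely benign` to benign. Composite submitter labels joined by `/` (e.g.
#' `Pathogenic/Likely pathogenic`) collapse when every part falls on the same
#' side. Uncertain significance, conflicting interpretations, `not provided`,
#' any unrecognized label, and any record below the review-star floor are
#' ineligible for benchmarking.
#'
#' @param raw_label Character vector of clinical significance labels.
#' @param stars Integer vector of review-status stars (0–4), recycled.
#' @param min_stars Minimum stars for eligibility (default 1, i.e. assertion
#'   criteria provided).
#' @param with_reason If `TRUE`, return a tibble with the collapsed `status`
#'   and the `reason` a record was ruled ineligible (`NA` otherwise).
#' @return Factor with levels `pathogenic`, `benign`, `ineligible` (or a
#'   tibble when `with_reason = TRUE`).
#' @examples
#' collapse_clinical(c("Likely pathogenic", "Benign", "Uncertain significance"),
#'                   stars = c(1, 2, 3))
#' @export
collapse_clinical <- function(raw_label, stars, min_stars = 1,
                              with_reason = FALSE) {
  n <- max(length(raw_label), length(stars))
  raw_label <- rep_len(raw_label, n)
  stars <- rep_len(stars, n)

  side_of <- function(lab) {
    lab <- tolower(trimws(lab))
    parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    one <- function(p) {
      if (p %in% c("pathogenic", "likely pathogenic")) "pathogenic"
      else if (p %in% c("benign", "likely benign")) "benign"
      else NA_character_
    }
    sides <- vapply(parts, one, character(1))
    if (length(sides) > 0 && !anyNA(sides) && length(unique(sides)) == 1) {
      sides[[1]]
    } else NA_character_
  }

  status <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    side <- if (is.na(raw_label[i])) NA_character_ else side_of(raw_label[i])
    if (is.na(side)) {
      status[i] <- "ineligible"
      reason[i] <- sprintf("non-definitive label '%s'", raw_label[i])
    } else if (is.na(stars[i]) || stars[i] < min_stars) {
      status[i] <- "ineligible"
      reason[i] <- sprintf("review status below %d star(s)", min_stars)
    } else {
      status[i] <- side
    }
  }
  status <- factor(status, levels = CLINICAL_LEVELS)
  if (with_reason) tibble::tibble(status = status, reason = reason) else status
}

#' Attach predicted class and collapsed clinical status to a cohort
#'
#' @param cohort Cohort tibble from [assemble_cohort()] (columns `score`,
#'   `raw_label`, `stars`).
#' @param cfg A [classifier_config()].
#' @param min_stars Review-star floor for clinical eligibility.
#' @return The cohort with `predicted_class` and `clinical_status` columns;
#'   variants with no matched clinical record get status `absent`.
#' @export
classify_cohort <- function(cohort, cfg = classifier_config(), min_stars = 1) {
  cohort$predicted_class <- classify_score(cohort$score, cfg)
  status <- factor(rep("absent", nrow(cohort)), levels = CLINICAL_LEVELS)
  has_clinical_cols <- all(c("raw_label", "stars") %in% names(cohort))
  has <- if (has_clinical_cols) !is.na(cohort$raw_label) else rep(FALSE, nrow(cohort))
  if (any(has)) {
    status[has] <- collapse_clinical(cohort$raw_label[has], cohort$stars[has],
                                     min_stars = min_stars)
  }
  cohort$clinical_status <- status
  cohort
}
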
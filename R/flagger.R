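#' Thresholds for misclassification suspicion rules
#'
#' The suspicion framework is directional — a benign call is suspect when the
#' variant looks like a pathogenic one (rare, high CADD, no homozygotes) and a
#' pathogenic call is suspect when it looks benign (common, low CADD, or
#' homozygotes present). The cutoffs operationalizing "rare"/"common" and
#' "high"/"low" are this package's own, chosen from the scale of the
#' concordant groups (true positives' mean allele frequency sits below 1e-4;
#' false-negative CADD means sit near 25 versus ~14 for true negatives), and
#' are meant to be tuned per application.
#'
#' @param af_low_max Allele frequency at or below which a variant counts as
#'   rare (default 1e-4).
#' @param af_high_min Allele frequency at or above which a variant counts as
#'   common (default 1e-3).
#' @param cadd_high_min CADD phred at or above which impact counts as high
#'   (default 20).
#' @param cadd_low_max CADD phred at or below which impact counts as low
#'   (default 15).
#' @param max_homozygotes_for_fn Maximum homozygote count compatible with a
#'   suspected false negative (default 0).
#' @return Validated list of class `missbench_flag_thresholds`.
#' @export
flag_thresholds <- function(af_low_max = 1e-4, af_high_min = 1e-3,
                            cadd_high_min = 20, cadd_low_max = 15,
                            max_homozygotes_for_fn = 0) {
  if (af_low_max > af_high_min || cadd_low_max > cadd_high_min) {
    stopf("missbench_error_config",
          "require af_low_max <= af_high_min and cadd_low_max <= cadd_high_min")
  }
  structure(list(af_low_max = af_low_max, af_high_min = af_high_min,
                 cadd_high_min = cadd_high_min, cadd_low_max = cadd_low_max,
                 max_homozygotes_for_fn = max_homozygotes_for_fn),
            class = "missbench_flag_thresholds")
}

#' Flag predictions suspected of being misclassified
#'
#' A predicted-benign variant is flagged `SUSPECT_FALSE_NEGATIVE` only when
#' it is rare AND has a high CADD score AND has no (or at most the configured
#' number of) homozygotes — the conjunction reflects that all three
#' pathogenic-like signals must agree before doubting a benign call. A
#' predicted-pathogenic variant is flagged `SUSPECT_FALSE_POSITIVE` when it
#' is common OR has a low CADD score OR has any homozygote — any single
#' benign-like signal suffices to warrant a second look. Ambiguous
#' predictions are never flagged.
#'
#' @param cohort Cohort tibble with `predicted_class`, `allele_frequency`,
#'   `cadd_phred`, `homozygote_count` (a one-row tibble works for a single
#'   variant).
#' @param th A [flag_thresholds()].
#' @return The cohort with `flag_kind` (`SUSPECT_FALSE_NEGATIVE`,
#'   `SUSPECT_FALSE_POSITIVE` or `NONE`) and `flag_reasons` (`;`-joined
#'   satisfied rules, empty when `NONE`).
#' @export
suspect_misclassification <- function(cohort, th = flag_thresholds()) {
  need <- c("predicted_class", "allele_frequency", "cadd_phred",
            "homozygote_count")
  absent <- setdiff(need, names(cohort))
  if (length(absent) > 0) {
    stopf("missbench_error_missing_field",
          "cannot evaluate flags: missing field(s) %s",
          paste(absent, collapse = ", "))
  }
  na_fields <- need[vapply(need, function(f) anyNA(cohort[[f]]), logical(1))]
  if (length(na_fields) > 0) {
    stopf("missbench_error_missing_field",
          "cannot evaluate flags: missing values in %s",
          paste(na_fields, collapse = ", "))
  }

  kind <- rep("NONE", nrow(cohort))
  reasons <- rep("", nrow(cohort))
  pc <- as.character(cohort$predicted_class)
  af <- cohort$allele_frequency
  cadd <- cohort$cadd_phred
  hom <- cohort$homozygote_count

  rare <- af <= th$af_low_max
  high_cadd <- cadd >= th$cadd_high_min
  no_hom <- hom <= th$max_homozygotes_for_fn
  fn_hit <- pc == "benign" & rare & high_cadd & no_hom
  kind[fn_hit] <- "SUSPECT_FALSE_NEGATIVE"
  reasons[fn_hit] <- sprintf(
    "AF<=%g; CADD>=%g; homozygotes<=%d",
    th$af_low_max, th$cadd_high_min, th$max_homozygotes_for_fn)

  common <- af >= th$af_high_min
  low_cadd <- cadd <= th$cadd_low_max
  has_hom <- hom >= 1
  fp_hit <- pc == "pathogenic" & (common | low_cadd | has_hom)
  for (i in which(fp_hit)) {
    r <- c(if (common[i]) sprintf("AF>=%g", th$af_high_min),
           if (low_cadd[i]) sprintf("CADD<=%g", th$cadd_low_max),
           if (has_hom[i]) "homozygotes>=1")
    kind[i] <- "SUSPECT_FALSE_POSITIVE"
    reasons[i] <- paste(r, collapse = "; ")
  }

  cohort$flag_kind <- kind
  cohort$flag_reasons <- reasons
  cohort
}

#' Build a per-metric envelope from reference variants
#'
#' Summarizes a reference set (typically well-characterized hypomorphic
#' variants of one gene) into min/median/max per population metric. The
#' median of an even-sized set is the mean of the two central order
#' statistics. A single-variant reference (min = median = max) gives a
#' named-comparator profile.
#'
#' @param references Tibble with `allele_frequency`, `homozygote_count`,
#'   `cadd_phred` (e.g. from [read_population_table()]).
#' @return List of class `missbench_profile`: one `c(min, median, max)`
#'   vector per metric, plus `n_reference`.
#' @export
build_profile <- function(references) {
  if (is.null(nrow(references)) || nrow(references) < 1) {
    stopf("missbench_error_undefined", "profile needs >= 1 reference variant")
  }
  env <- function(x) c(min = min(x), median = median(x), max = max(x))
  structure(list(
    allele_frequency = env(references$allele_frequency),
    homozygote_count = env(references$homozygote_count),
    cadd_phred = env(references$cadd_phred),
    n_reference = nrow(references)
  ), class = "missbench_profile")
}

#' Compare a query variant's metrics to a reference profile
#'
#' Inclusive range checks per metric; the overall verdict is true only when
#' every metric lies within the reference envelope.
#'
#' @param query One-row tibble (or named list) with `allele_frequency`,
#'   `homozygote_count`, `cadd_phred`.
#' @param profile A [build_profile()] result.
#' @return List with `per_metric` (tibble: metric, value, min, max, within)
#'   and `overall` (logical).
#' @export
compare_to_profile <- function(query, profile) {
  metrics <- c("allele_frequency", "homozygote_count", "cadd_phred")
  rows <- lapply(metrics, function(m) {
    v <- as.numeric(query[[m]][1])
    rng <- profile[[m]]
    tibble::tibble(metric = m, value = v,
                   min = unname(rng["min"]), max = unname(rng["max"]),
                   within = v >= rng[["min"]] && v <= rng[["max"]])
  })
  per_metric <- dplyr::bind_rows(rows)
  list(per_metric = per_metric, overall = all(per_metric$within))
}
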
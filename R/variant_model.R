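#' @include utils.R
NULL

# canonical 20-residue alphabet; Sec (U) / Pyl (O) are outside the predictor's
# substitution space and are rejected at parse time
AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
         Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
         Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
         Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
AA1 <- unname(AA3)
NONCANONICAL3 <- c(Sec = "U", Pyl = "O")

#' Parse a protein-level substitution in HGVS or shorthand notation
#'
#' Accepts three-letter HGVS protein changes with or without the `p.` prefix
#' (`p.Gly1961Glu`, `Arg2030Gln`) and one-letter shorthand (`G12D`), and
#' normalizes three-letter codes to the one-letter alphabet. Only missense
#' substitutions between the 20 canonical residues are accepted: nonsense
#' (`Ter`, `*`), frameshift, deletion/duplication/insertion, extension, and
#' synonymous (`=` or identical reference and alternate residues) changes are
#' rejected as non-missense; anything unrecognizable is a parse failure.
#'
#' @param text Character vector of protein changes.
#' @param strict If `TRUE` (default) the first invalid entry aborts with a
#'   classed condition: `missbench_error_not_missense` for well-formed
#'   non-missense changes, `missbench_error_parse` otherwise. If `FALSE`,
#'   invalid entries yield `NA` fields plus a `reason` column.
#' @return A tibble with one row per input: `ref_aa`, `position`, `alt_aa`
#'   (and `ok`, `reason` when `strict = FALSE`).
#' @examples
#' parse_protein_change("p.Gly1961Glu")
#' parse_protein_change(c("G12D", "Pro1948Leu"))
#' @export
parse_protein_change <- function(text, strict = TRUE) {
  if (length(text) == 0) stopf("missbench_error_parse", "empty protein change")
  empty <- is.na(text) | !nzchar(trimws(text))
  if (strict && any(empty)) stopf("missbench_error_parse", "empty protein change")
  x <- trimws(text)
  x[empty] <- "<empty>"
  x <- sub("^p\\.", "", x)
  x <- sub("^\\((.*)\\)$", "\\1", x)  # tolerate predicted-consequence parens

  ref <- rep(NA_character_, length(x))
  pos <- rep(NA_integer_, length(x))
  alt <- rep(NA_character_, length(x))
  reason <- rep(NA_character_, length(x))
  kind <- rep("parse", length(x))  # error kind when invalid

  not_missense <- function(why) list(why = why, kind = "not_missense")

  for (i in seq_along(x)) {
    s <- x[[i]]
    if (grepl("(fs|del|dup|ins|ext)", s)) {
      reason[i] <- "not a missense substitution (fs/del/dup/ins/ext)"
      kind[i] <- "not_missense"
      next
    }
    m3 <- regmatches(s, regexec("^([A-Z][a-z]{2})([0-9]+)(Ter|\\*|=|[A-Z][a-z]{2})$", s))[[1]]
    m1 <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*=])$", s))[[1]]
    if (length(m3) == 4) {
      if (m3[4] %in% c("Ter", "*", "=")) {
        reason[i] <- "not a missense substitution (nonsense/synonymous)"
        kind[i] <- "not_missense"
        next
      }
      if (m3[2] %in% names(NONCANONICAL3) || m3[4] %in% names(NONCANONICAL3)) {
        reason[i] <- sprintf("non-canonical residue code in '%s'", s)
        next
      }
      if (!(m3[2] %in% names(AA3)) || !(m3[4] %in% names(AA3))) {
        reason[i] <- sprintf("unknown three-letter residue code in '%s'", s)
        next
      }
      r <- AA3[[m3[2]]]; a <- AA3[[m3[4]]]; p <- suppressWarnings(as.integer(m3[3]))
    } else if (length(m1) == 4) {
      if (m1[4] %in% c("*", "=")) {
        reason[i] <- "not a missense substitution (nonsense/synonymous)"
        kind[i] <- "not_missense"
        next
      }
      if (m1[2] %in% NONCANONICAL3 || m1[4] %in% NONCANONICAL3) {
        reason[i] <- sprintf("non-canonical residue code in '%s'", s)
        next
      }
      if (!(m1[2] %in% AA1) || !(m1[4] %in% AA1)) {
        reason[i] <- sprintf("unknown residue code in '%s'", s)
        next
      }
      r <- m1[2]; a <- m1[4]; p <- suppressWarnings(as.integer(m1[3]))
    } else {
      reason[i] <- sprintf("malformed protein change '%s'", s)
      next
    }
    if (is.na(p) || p < 1) {
      reason[i] <- sprintf("invalid residue position in '%s'", s)
      next
    }
    if (r == a) {
      reason[i] <- sprintf("not a missense substitution ('%s' is synonymous)", s)
      kind[i] <- "not_missense"
      next
    }
    ref[i] <- r; pos[i] <- p; alt[i] <- a
  }

  bad <- which(!is.na(reason))
  if (strict && length(bad) > 0) {
    i <- bad[1]
    stopf(paste0("missbench_error_", kind[i]), "%s", reason[i])
  }
  out <- tibble::tibble(ref_aa = ref, position = pos, alt_aa = alt)
  if (!strict) {
    out$ok <- is.na(reason)
    out$reason <- reason
  }
  out
}

#' Format a parsed substitution as one-letter shorthand
#'
#' @param parsed Tibble from [parse_protein_change()].
#' @return Character vector like `"G1961E"`.
#' @export
format_protein_change <- function(parsed) {
  paste0(parsed$ref_aa, parsed$position, parsed$alt_aa)
}

#' Build protein-level variant keys
#'
#' The key joining predictor, clinical and population records is the uppercased
#' gene symbol plus the normalized one-letter substitution, e.g. `ABCA4:G1961E`.
#' Matching is case-insensitive on the gene and exact on the substitution;
#' genomic coordinates never participate in joining.
#'
#' @param gene Character vector of gene symbols (whitespace tolerated).
#' @param change Character vector of protein changes, recycled against `gene`.
#' @param strict Passed to [parse_protein_change()]; when `FALSE`, rows whose
#'   change fails to parse get an `NA` key.
#' @return Character vector of keys (with `NA` for failed rows if
#'   `strict = FALSE`).
#' @examples
#' make_key("abca4", "p.Pro1948Leu")
#' @export
make_key <- function(gene, change, strict = TRUE) {
  if (any(is.na(gene) | !nzchar(trimws(gene)))) {
    stopf("missbench_error_parse", "empty gene symbol")
  }
  n <- max(length(gene), length(change))
  gene <- rep_len(toupper(trimws(gene)), n)
  change <- rep_len(change, n)
  parsed <- parse_protein_change(change, strict = strict)
  key <- paste0(gene, ":", format_protein_change(parsed))
  if (!strict) key[!parsed$ok] <- NA_character_
  key
}

#' Match predictor and clinical key sets
#'
#' Performs the exact protein-level key join between a predictor score set and
#' a clinical annotation set. Clinical keys left unmatched by the exact join
#' are looked up in an optional override map — the mechanized counterpart of
#' manual reconciliation of transcript-versioning discrepancies. Override
#' targets absent from the predictor set are warned about and left unmatched.
#'
#' @param predictor_keys,clinical_keys Character vectors of keys
#'   (deduplicated internally; gene case normalized).
#' @param overrides Optional named character vector mapping a clinical key to
#'   the predictor key it should be reconciled to.
#' @return A list with `matched` (tibble: `clinical_key`, `predictor_key`,
#'   `via_override`) and `report` (tibble of counts: `matched`,
#'   `unmatched_predictor`, `unmatched_clinical`, `reconciled_by_override`).
#'   `matched + unmatched_clinical` always equals the number of distinct
#'   clinical keys offered.
#' @export
match_records <- function(predictor_keys, clinical_keys, overrides = NULL) {
  pk <- unique(toupper(predictor_keys))
  ck <- unique(toupper(clinical_keys))

  direct <- ck[ck %in% pk]
  leftover <- setdiff(ck, direct)

  via <- character(0)
  via_target <- character(0)
  if (length(overrides) > 0 && length(leftover) > 0) {
    ov <- stats::setNames(toupper(overrides), toupper(names(overrides)))
    hit <- leftover[leftover %in% names(ov)]
    for (k in hit) {
      tgt <- ov[[k]]
      if (tgt %in% pk) {
        via <- c(via, k)
        via_target <- c(via_target, tgt)
      } else {
        warn(sprintf("override target '%s' for clinical key '%s' absent from predictor set; left unmatched",
                     tgt, k))
      }
    }
  }

  matched <- tibble::tibble(
    clinical_key = c(direct, via),
    predictor_key = c(direct, via_target),
    via_override = c(rep(FALSE, length(direct)), rep(TRUE, length(via)))
  )
  n_matched <- nrow(matched)
  n_unmatched_pred <- length(setdiff(pk, matched$predictor_key))
  report <- tibble::tibble(
    matched = n_matched,
    unmatched_predictor = n_unmatched_pred,
    unmatched_clinical = length(ck) - n_matched,
    reconciled_by_override = length(via)
  )
  list(matched = matched, report = report)
}
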
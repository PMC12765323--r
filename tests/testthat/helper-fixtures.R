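# shared fixtures built in code

# write a small TSV and return its path
write_fixture <- function(lines, name = "fixture.tsv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# the bundled per-gene reference counts as a confusion tibble
top20_confusion <- function() {
  t1 <- read_reference("ird_top20_confusion.tsv")
  dplyr::bind_rows(lapply(seq_len(nrow(t1)), function(i) {
    confusion_table(tp = t1$tp[i], fp = t1$fp[i], tn = t1$tn[i],
                    fn = t1$fn[i], scope = t1$gene[i])
  }))
}

# bundled cohort-level reference counts (one row)
cohort_confusion <- function() read_reference("ird_cohort_confusion.tsv")

# bundled hypomorph reference set with predicted classes attached
hypomorph_cohort <- function() {
  h <- read_reference("abca4_hypomorphs.tsv")
  names(h)[names(h) == "am_pathogenicity"] <- "score"
  classify_cohort(h)
}

# small fully-annotated cohort for concordance/discrimination tests
toy_cohort <- function(seed = 101, n = 400) {
  cfg <- synthetic_config(seed = seed, n_variants = n, n_genes = 4,
                          p_labeled_pathogenic = 1, p_labeled_benign = 1)
  g <- generate_cohort(cfg)
  cohort <- g$truth[, c("key", "gene", "protein_change", "score",
                        "allele_frequency", "homozygote_count", "cadd_phred")]
  cohort$raw_label <- g$truth$label
  cohort$stars <- g$truth$stars
  cohort <- classify_cohort(cohort, min_stars = 0)
  cohort$confusion <- assign_confusion(cohort$predicted_class,
                                       cohort$clinical_status)
  cohort
}
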
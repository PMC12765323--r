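test_that("predictor reader filters to the panel and validates scores", {
  path <- write_fixture(c(
    "# provenance comment",
    "gene\tprotein_variant\tam_pathogenicity",
    "ABCA4\tGly1961Glu\t0.853",
    "ABCA4\tAsn1868Ile\t0.223",
    "USH2A\tCys3307Trp\t0.924",
    "RHO\tPro23His\t0.9",
    "TTN\tAla2Val\t0.5"))
  recs <- read_predictor_table(path, panel = c("ABCA4", "USH2A", "RHO"))
  expect_equal(nrow(recs), 4)
  expect_equal(attr(recs, "n_read"), 5)
  expect_true(all(recs$score >= 0 & recs$score <= 1))
  expect_equal(recs$key[1], "ABCA4:G1961E")

  bad <- write_fixture(c("gene\tprotein_variant\tam_pathogenicity",
                         "ABCA4\tGly1961Glu\t1.2"))
  expect_error(read_predictor_table(bad), class = "missbench_error_row")
  noscore <- write_fixture(c("gene\tprotein_variant",
                             "ABCA4\tGly1961Glu"))
  expect_error(read_predictor_table(noscore), class = "missbench_error_schema")
  expect_error(read_predictor_table(noscore), "am_pathogenicity")
})

test_that("clinical reader keeps raw labels and skips unusable rows", {
  path <- write_fixture(c(
    "gene\tprotein_change\tclinical_significance\treview_stars",
    "ABCA4\tGly1961Glu\tPathogenic\t2",
    "ABCA4\tAsn1868Ile\tConflicting interpretations of pathogenicity\t1",
    "ABCA4\tArg2030Ter\tPathogenic\t2",
    "USH2A\tnot-a-change\tBenign\t1",
    "RHO\tPro23His\tLikely pathogenic\t1"))
  expect_message(recs <- read_clinical_table(path), "skipped 2 row")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$raw_label[2], "Conflicting interpretations of pathogenicity")
  nostars <- write_fixture(c("gene\tprotein_change\tclinical_significance",
                             "ABCA4\tGly1961Glu\tPathogenic"))
  expect_error(read_clinical_table(nostars), class = "missbench_error_schema")
  badstars <- write_fixture(c("gene\tprotein_change\tclinical_significance\treview_stars",
                              "ABCA4\tGly1961Glu\tPathogenic\t7"))
  expect_error(read_clinical_table(badstars), class = "missbench_error_row")
})

test_that("population reader parses scientific notation and rejects bad counts", {
  recs <- read_population_table(reference_path("abca4_hypomorphs.tsv"))
  expect_equal(nrow(recs), 9)
  expect_equal(recs$allele_frequency[recs$protein_change == "N1868I"], 0.0558)
  expect_equal(recs$homozygote_count[recs$protein_change == "N1868I"], 2989L)
  bad <- write_fixture(c(
    "gene\tprotein_change\tallele_frequency\thomozygote_count\tcadd_phred",
    "ABCA4\tGly1961Glu\t3.41e-3\t-1\t26.2"))
  expect_error(read_population_table(bad), class = "missbench_error_row")
})

test_that("duplicate keys keep the first record with a warning", {
  path <- write_fixture(c("gene\tprotein_variant\tam_pathogenicity",
                          "ABCA4\tGly1961Glu\t0.853",
                          "abca4\tp.Gly1961Glu\t0.111"))
  expect_warning(recs <- read_predictor_table(path), "duplicate")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$score, 0.853)
})

test_that("cohort assembly is the population inner join with clinical attach", {
  predictor <- tibble::tibble(
    key = c("G1:A1V", "G1:A2V", "G2:A1V", "G2:A2V"),
    gene = c("G1", "G1", "G2", "G2"),
    protein_change = c("A1V", "A2V", "A1V", "A2V"),
    score = c(0.9, 0.1, 0.5, 0.7))
  population <- tibble::tibble(
    key = c("G1:A1V", "G2:A2V", "G3:A1V"),
    allele_frequency = c(1e-4, 1e-2, 0.2),
    homozygote_count = c(0L, 5L, 100L),
    cadd_phred = c(25, 10, 3))
  clinical <- tibble::tibble(key = "G1:A1V", raw_label = "Pathogenic",
                             stars = 2L)
  asm <- assemble_cohort(predictor, clinical, population)
  expect_equal(nrow(asm$cohort), 2)
  expect_equal(sum(!is.na(asm$cohort$raw_label)), 1)
  expect_equal(asm$report$n_predictor_without_population, 2)
  expect_true(nrow(asm$cohort) <= min(nrow(predictor), nrow(population)))

  disjoint <- tibble::tibble(key = "G9:A1V", allele_frequency = 0.1,
                             homozygote_count = 0L, cadd_phred = 1)
  expect_error(assemble_cohort(predictor, clinical, disjoint),
               class = "missbench_error_empty_cohort")
})

test_that("generated synthetic tables pass the readers unchanged", {
  dir <- withr::local_tempdir()
  g <- generate_cohort(synthetic_config(seed = 5, n_variants = 1000,
                                        n_genes = 5), dir)
  pred <- read_predictor_table(g$paths$predictor, panel = g$panel)
  expect_equal(nrow(pred), 1000)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  clin <- read_clinical_table(g$paths$clinical)
  pop <- read_population_table(g$paths$population)
  asm <- assemble_cohort(pred, clin, pop)
  expect_equal(nrow(asm$cohort), 1000)  # every member has population metrics
  expect_true(all(asm$cohort$allele_frequency > 0))
  expect_equal(asm$report$clinical_match$matched, nrow(clin))
})

test_that("a written cohort round-trips through read_cohort", {
  cohort <- toy_cohort(seed = 9, n = 120)
  path <- file.path(withr::local_tempdir(), "cohort.tsv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})
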
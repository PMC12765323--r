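---
title: "Benchmarking missense pathogenicity predictions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missense pathogenicity predictions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missbench)
```

## The problem and the measurement model

`missbench` measures how well a precomputed missense pathogenicity score
agrees with curated clinical assertions over a gene panel, and what the
population genetics of the discordant variants looks like. The unit of
analysis is a protein-level variant: an uppercased gene symbol plus a
normalized one-letter amino-acid substitution (`ABCA4:G1961E`). All three
input tables — predictor scores, clinical annotations, population metrics —
are joined on that key alone. Genomic coordinates, when present, ride along
as annotation; they never participate in matching, because the predictor's
published scores are per representative transcript and protein-level HGVS
is the notation shared by all three sources. Residual cross-source
discrepancies (transcript versioning, isoform numbering) are handled by an
explicit override map: a named list sending a clinical key to the predictor
key it should reconcile to, with full accounting of what matched, what
didn't, and what was reconciled.

The analysis cohort is the inner join of predictor and population tables:
only variants with population data enter, so every member has a positive
allele frequency by construction. This mirrors standard practice (population
metrics are needed downstream for every member) but means ultra-rare
variants absent from population databases are never benchmarked — a genuine
sampling-frame limitation that any interpretation of the resulting
sensitivity should keep in mind.

## Classification and eligibility

Scores are banded by the predictor's established high-precision cutoffs.
These are usually quoted as three-decimal intervals (0.000–0.333 benign,
0.334–0.564 ambiguous, 0.565–1.000 pathogenic), which leaves the open
interval (0.333, 0.334) undefined; we therefore adopt the continuous rule

* benign ⇔ score < `benign_max` (default 0.34),
* pathogenic ⇔ score > `pathogenic_min` (default 0.564),
* ambiguous otherwise,

which is monotone, partitions [0, 1], and reproduces every three-decimal
assignment in the bundled ABCA4 reference set (0.343 → ambiguous, 0.366 →
ambiguous, 0.326 → benign). Both cutoffs are configurable
(`classifier_config()`), as is the review-star floor for clinical
eligibility (`min_stars`, default 1 = "assertion criteria provided").
Clinical labels collapse case-insensitively; composite submitter labels
(`Pathogenic/Likely pathogenic`) collapse when all parts agree. Everything
non-definitive is ineligible with a recorded reason — never an error —
because ineligible records still count in the filtering funnel.

## Concordance metrics and uncertainty

Each evaluable variant receives one of six confusion labels (TP/FN/FP/TN
plus one ambiguous bucket per clinical class). Two policies turn these into
metrics: the primary analysis excludes ambiguous predictions from every
denominator; the sensitivity analysis counts them as errors (false
negatives on pathogenic variants, false positives on benign ones). The
package always computes both; excluding ambiguity can only look better, and
the gap between the policies is itself informative.

Confidence intervals are Wilson score intervals. The choice is deliberate:
per-gene tables routinely contain 22/22 or 1/1 proportions where Wald
intervals collapse, and the Wilson family reproduces sensible bounds at
those corners (lower bound 85.1% for 22/22, 20.7% for 1/1 at 95%
coverage). The implementation is the closed form, regression-tested against
`prop.test(correct = FALSE)` and an independent re-derivation to 1e-12.
Metrics with zero denominators are reported as explicitly undefined values
with a reason, never silent `NaN`s.

Panel summaries come in two flavors: micro (pool counts, then compute — used
for the FDR) and macro (compute per gene, then average the defined values).
For macro sensitivity, genes whose sensitivity is defined but zero (TP = 0
with FN > 0) are a reporting judgment call; published panel averages are
sometimes computed with such genes dropped. Both conventions are
implemented (`macro_rule = "defined"` or `"drop_zero_tp"`), and on the
bundled top-20 table they differ by about four percentage points (79.1% vs
83.2%) — a good illustration of why the rule must be stated.

AUROC is computed from the midrank Mann–Whitney statistic, equal to the
trapezoidal ROC area and correct under the heavy ties of three-decimal
score grids; AUPRC is the stepwise average precision over distinct
thresholds. Both are verified against brute-force pair counting and an
independent ROC implementation in the test suite.

## Discrimination of misclassified variants

Four Welch t tests compare log10 allele frequency and CADD phred between TP
and FP variants and between TN and FN variants, with Bonferroni-corrected
significance at 0.05/4 = 1.25×10⁻². Design choices worth stating:

* The log transform applies to allele frequency only; CADD is already
  phred-scaled. Natural-scale AF means are reported alongside the tested
  log-scale means, since both are conventional in reports.
* AF = 0 cannot occur (population-presence is a cohort invariant), so no
  pseudo-count is needed; an assertion guards this.
* p-values are two-sided; the Welch–Satterthwaite degrees of freedom are
  not rounded. The statistic is implemented from the closed formulas so the
  zero-variance degenerate case yields a classed "undefined" error rather
  than a generic failure; `stats::t.test` serves as the independent
  cross-check in tests.
* Comparisons with fewer than two members in a group are reported as
  not-computable rows, keeping the four-row report shape stable.

Homozygote rates — the share of each confusion group with at least one
reported homozygote — complete the discrimination picture; they need no
test statistic to be useful (rates differ by an order of magnitude between
concordant-benign and concordant-pathogenic groups).

## The suspicion flagger and hypomorph profiles

The flagging rules are directional: benign calls are doubted only when
*all* pathogenic-like signals agree (rare AND high CADD AND no
homozygotes), pathogenic calls when *any* benign-like signal appears
(common OR low CADD OR homozygotes present). The asymmetry is intentional —
an apparent benign-like signal is individually strong evidence against
pathogenicity, whereas pathogenic-like signals are individually weak.
The numeric cutoffs (rare ≤ 1e-4, common ≥ 1e-3, high CADD ≥ 20, low
CADD ≤ 15, at most 0 homozygotes) are this package's own operating points,
chosen from the scale separation between concordant groups in published
benchmark data, and are prominently configurable; tightening the
false-negative thresholds provably never flags more variants.

Known hypomorphic variants — partial loss-of-function alleles with
unusually high population frequency for pathogenic variants — are the
hardest class for structure-informed predictors and a documented source of
false negatives. `build_profile()` summarizes a reference hypomorph set
into per-metric min/median/max envelopes; `compare_to_profile()` performs
inclusive range checks. "In range" is interpreted as within the [min, max]
envelope of the full reference set; comparing against a single named
comparator is the special case of a one-variant profile, so both readings
are available. Note the flagger's behavior on hypomorphs is deliberately
two-edged: a true hypomorph that the predictor scores pathogenic will often
trip the false-positive rule through its homozygotes — the flag means
"needs human review", not "wrong".

## The synthetic generator

The generator emulates what the analysis consumes, not the genome: each of
`n_variants` synthetic variants draws a latent truth class (pathogenic with
probability 0.237), then class-conditional score, log10 allele frequency
(truncated normal on [−8, 0], so every variant is population-present), CADD
(normal truncated at 0), and a homozygote count from
Binomial(`pop_size`, AF²) — the Hardy–Weinberg expectation at the default
diploid population size of 800,000, the scale of current population
aggregates. Default parameters were fixed once, from published summaries:

* Score shapes Beta(0.811, 0.346) (pathogenic truth) and
  Beta(0.177, 1.402) (benign truth) were least-squares fitted so the three
  score bands carry ~69.7/12.2/18.1% of pathogenic-truth mass and
  ~5.5/6.6/87.8% of benign-truth mass, the shares observed in a large
  clinical benchmark; they imply expected sensitivity 79.4% and
  specificity 94.1% under the exclude policy.
* Truth prevalence 0.237 reproduces the observed full-cohort predicted
  class shares (≈20.7% pathogenic calls); labeling probabilities 0.059
  (pathogenic truth) and 0.025 (benign truth) reproduce a ~3.3%
  definitively-labeled fraction with ~43% of labels pathogenic.
* AF models (log10 means −4.7 vs −2.8, SDs 1.0 vs 1.5) and CADD models
  (means 26.5 vs 14, SDs 4 vs 9) reflect the group separations reported
  between concordant pathogenic and benign variants.
* The label-error rate defaults to 0 so parameter-recovery tests are exact;
  it exists because clinical archives are a reference, not ground truth,
  and raising it shifts the closed-form expectations accordingly.

`expected_metrics()` returns the closed-form expected
sensitivity/specificity/FDR from the Beta CDFs (general mixture form, so it
stays correct with label errors). Review-star filtering removes labels
independently of the score and therefore cancels from these expectations.

What the generator does **not** emulate: linkage, per-population frequency
stratification, gene length variation, the correlation between score and
population metrics within a truth class, and the curation biases of real
archives. Passing recovery tests therefore demonstrates that the pipeline
computes what it claims on data satisfying its assumptions — not that any
predictor achieves those numbers on real cohorts.

## Numerical and reporting choices

* Percent values in reports round half-up (1 decimal for performance
  metrics, 2 for homozygote rates); published tables occasionally truncate
  instead, so tests compare printed values at ±0.01 where sources are
  internally inconsistent.
* Duplicate keys within a source keep the first record with a warning; a
  supplied canonical-transcript map takes precedence when the predictor
  table carries transcripts.
* Selenocysteine/pyrrolysine substitutions are rejected at parse time: they
  are outside the 20-residue substitution space predictors score.
* Determinism: every stochastic operation routes through a single seed in
  the generator config; re-running the pipeline on identical inputs is
  bitwise reproducible.

## Problem sizes

The bundled analysis scripts simulate 50,000 variants (yielding ≈1,600
definitive labels, comparable to real panel benchmarks); recovery tests
compare the pipeline's estimates with closed forms within three Monte-Carlo
standard errors at that size. The null calibration of the Bonferroni
procedure uses 1,000 replicate cohorts of 120 variants. These sizes give
standard errors a few times smaller than the effects of interest while
keeping a full replay of the analysis in the minutes range on a laptop.

## Known limitations

* Protein-level matching cannot distinguish distinct nucleotide variants
  producing the same substitution; the first record wins within a source.
* The HGVS grammar covered is deliberately minimal: missense substitutions
  only (no intronic, UTR, delins, extension syntax).
* Multi-submitter clinical records must be pre-reduced to one label per
  variant upstream; the package documents, but does not resolve, that
  aggregation.
* The flagger's default thresholds are operating points, not calibrated
  probabilities; they should be tuned (and their yield audited) per panel.
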
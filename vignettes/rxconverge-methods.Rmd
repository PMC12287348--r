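---
title: "Methods: disproportionality, permutation enrichment, and genetic convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, permutation enrichment, and genetic convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxconverge)
```

## Overview

`rxconverge` chains five analyses: disproportionality-based signal detection
in a spontaneous-reporting database, permutation tests for class-enriched
target genes, permutation tests for directional mechanism of action,
enrichment of target-gene sets in gene-level genetic risk, and the
intersection of the evidence streams. This vignette documents the models and
assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer should know about. Every empirical claim here is
recomputed by the test suite or the acceptance script; nothing is quoted
from elsewhere.

## Signal detection

A report database is a long table (`report_id`, `medication_id`, `term_id`,
`term_role`). Reports carrying more than one medication are removed first —
disproportionality on polypharmacy reports cannot attribute the effect to a
single agent — and statistics are computed for every observed
medication/side-effect pair on the retained reports.

For the 2×2 table (a, b, c, d):

* **PRR** = [a/(a+b)] / [c/(c+d)]. The comparator excludes the index
  medication's reports. The source literature does not print the formula;
  this is the standard definition. Numerically we evaluate
  a·(c+d) / ((a+b)·c), which is exact for integer-valued cells, so the
  inclusive boundary PRR ≥ 3 compares cleanly (0.3/0.1 in floating point is
  *not* 3). PRR is `Inf` when c = 0 with a > 0 — maximal disproportionality,
  which deliberately *passes* the PRR criterion — and 0 when a = 0.
* **Yates χ²** uses the margin formula with the continuity correction
  clamped at zero (`max(0, |ad−bc|−N/2)`), preventing over-correction on
  tiny tables; it errors on zero margins, and a pair whose table has a zero
  margin can never be a signal.
* **Criteria**: a ≥ 3, PRR ≥ 3, χ² ≥ 4, all boundaries inclusive. The
  psychosis-term and antipsychotic-exclusion filters are applied *after*
  the statistics, matching the published step order; the term list and the
  exclusion list are plain inputs, standing in for curated vocabularies.

## Target-gene permutation

The class sample size is the number of class medications with ≥ 1 link
(curated and predicted links collapse to one medication–gene pair). Per
iteration one class-sized set is sampled uniformly without replacement from
the background — class medications included, mirroring the published
background definitions — and scores **all** genes jointly. Whether the
sampled set is shared across genes or redrawn per gene is not decidable from
the source; joint scoring is marginally identical and ~10³ times cheaper, so
it is the implementation. The empirical p-value is the fraction of null
proportions *strictly greater* than the observed proportion (the published
wording). Strict comparison can yield p = 0 (e.g. for universally targeted
genes whose observed proportion equals the null maximum); a `"geq"` mode is
provided and both are tested against exhaustive subset enumeration. No
multiple-testing correction is applied across genes (raw 0.05 cutoff), as in
the source procedure; this is recorded in the result attributes.

`enumerate_target_null()` is the independent oracle (all C(|background|,
n) subsets); it exists for testing only and is never substituted for the
sampled permutation.

## Mechanism of action

Labels collapse case-insensitively into **activating** (agonist, activator,
inducer, potentiator, positive allosteric modulator, positive modulator,
stimulator) and **inhibiting** (inhibitor, antagonist, blocker, negative
modulator, inactivator, suppressor, weak inhibitor, inhibitory allosteric
modulator); anything else is unknown. Labels come exclusively from
curated-source links. The per-gene proportion denominator is the number of
class medications with *any* labeled link — the literal reading of the
source phrasing — so a medication whose only labels are direction-unknown
still counts; a `denominator = "known_direction"` mode excludes such
medications, since the source is ambiguous on this point. A medication
counts at most once per (gene, direction). Both direction nulls share the
per-iteration sampled sets, exactly as the two recorded proportions do in
the published procedure. Shared target genes are `opposed` when a
significant direction in one class has its opposite significant in the
other, `same` on a common significant direction, and `mixed` when both hold
(possible because one class can have both directions significant for a
gene).

## Genetic convergence

Risk tables are prepared by three rules applied in order: drop missing
p-values, drop *all* occurrences of duplicated gene symbols (full removal,
not keep-first — the conservative reading of the source rule), restrict to
drugged genes. Enrichment is a one-sided two-sample Wilcoxon on −log10 p
(targets greater), exact when both groups are ≤ 25 without ties, otherwise
the normal approximation with continuity correction; being rank-based it is
invariant to monotone transforms of the p column, which the tests verify.

High-confidence calls: rare-LoF genes with p < 2.14×10⁻⁶ (fixed exome-wide
threshold, strict), common-SNP genes with Bonferroni-adjusted p
(min(p·m, 1)) strictly below 0.05. The source is explicit that the rare
calls predate the drugged-gene restriction and ambiguous for the common
calls; the pipeline applies both to the unrestricted tables and exposes the
Bonferroni denominator `m` (default: the unrestricted common-table row
count). Triple evidence = propsychotic target ∧ rare high-confidence ∧
common high-confidence.

## Overlap statistics

Fold enrichment k·N/(n1·n2); hypergeometric upper tail P(X ≥ k); Fisher's
exact test on (k, n1−k, n2−k, N−n1−n2+k) reporting the conditional-MLE odds
ratio and the two-sided point-probability p, i.e. the `stats::fisher.test()`
convention the source itself used. The universe N is always an explicit
argument — the source never prints it, so no default would be defensible.
On the published worked table (170, 129, 67, 3417) the conditional MLE and
the sample OR agree within 1%. Note that for the fully-overlapping 3/3/3 in
6 table the two-sided p is 0.10 (both extreme tables have probability
1/20), not the one-sided 0.05.

## Synthetic data: the stated world

Defaults (`sim_config()`): 50,000 reports, 150 medications, 500 genes,
20 psychosis + 180 other side-effect terms, 30% multi-medication reports,
10 planted propsychotics with a 6-fold psychosis-term rate over a 1%
baseline, 8 planted antipsychotics, 30 mechanism genes (60% of them
"opposed" genes carrying activating labels from propsychotics and
inhibiting labels from antipsychotics), 2% background link density, 70%
label coverage, 40 planted risk genes per class with `risk_effect = 3`,
and 2 triple-evidence genes. With these numbers a planted pair expects
35,000/150 × 0.06 ≈ 14 co-reports — comfortably above the a ≥ 3 criterion —
which is why 150 (not more) medications define the default world; the
choice was fixed before any acceptance measurement.

Generative assumptions, and what they mean for a green test:

* Terms are sampled independently per term given the medication — no
  term–term correlation, no report covariates, no duplicate reports. A
  green planted-recovery test shows the procedure recovers marginal
  disproportionality, not that it is robust to confounding by
  polypharmacy or indication.
* Multi-medication reports (2–3 medications, uniform) exist only to
  exercise the single-medication filter.
* Every report must carry ≥ 1 side-effect term; reports drawing none
  receive one fallback term sampled proportionally to their rate vector.
  The fallback slightly dampens realized PRRs below the nominal rate
  ratio; the determinism test's closed-form oracle for the cell means
  accounts for it exactly: P(term) = p_t + Π_s(1−p_s) · p_t/Σp.
* Planted risk p-values use the power-function family U^(1+risk_effect):
  stochastically smaller, and exactly uniform at `risk_effect = 0`, which
  is what makes the Kolmogorov–Smirnov null check of the generator valid.
  Triple-evidence genes are additionally forced below the hard thresholds
  (rare: just under 2.14×10⁻⁶; common: under half of 0.05/n_genes), so
  pipeline recovery of the triple set tests the *intersection logic*, not
  the tail luck of the risk draw.
* Planted class–gene pairs are excluded from the background link grid so a
  background link can never contradict a planted action label; planted
  links are drawn with probability 0.9 per pair (fixed constant).
* One master seed drives everything through named sub-streams
  (`reports`, `links`, `risk`, per-stage permutation streams), mixed as
  `(|seed|·127 + offset·7919) mod (2³¹−1)`, so any component can be
  regenerated independently and identically.

## Lexicon normalization

Preprocessing lowercases, converts whitespace/special characters to
periods, collapses period runs, and trims (including boundary periods —
a small extension keeping tokenization clean and the operation idempotent).
All similarity methods derive from 2·M/(len1+len2) with M the matched
characters of a longest-matching-block decomposition (the behavior of the
cited ratio family, reimplemented so no external library is needed; block
tie-breaks are order-dependent in principle, so the score is evaluated in
both argument orders and the maximum taken, guaranteeing symmetry). Scores
are on [0, 1], matching the calibration windows that start at 0.5.
Tokenization splits on the period delimiter. The weighted method takes the
maximum of weighted per-method scores; the source does not print its
weights, so they are configurable with defaults (plain 1, token variants
0.95). Threshold calibration samples up to 10 matches per 0.1-wide window
from 0.5 upward (≤ 50 per method, top window first) and chooses the lowest
window bound whose cumulative precision is ≥ 0.9 — an explicit
operationalization of a manual-review judgment that cannot be reproduced
literally.

## Known limitations

* The permutation engine materializes a dense background × gene incidence
  matrix; fine for desk-scale worlds (≤ ~10³ × 10³), not for millions of
  links.
* The synthetic world has no reporting-rate heterogeneity across
  medications, no secular trends, and no correlated side-effect syndromes;
  null-calibration results transfer to real reporting data only with those
  caveats.
* The Wilcoxon exact/asymptotic switch at n = 25 follows standard practice;
  p-values for mid-sized tied data are approximate.
* `fisher_overlap_test` inherits `stats::fisher.test`'s conditional-MLE
  behavior; for extreme tables the MLE is reported as `Inf`/0 with no
  continuity adjustment, by design.
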
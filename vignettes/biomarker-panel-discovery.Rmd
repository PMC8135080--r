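---
title: "Methods: platelet proteomic biomarker panel discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: platelet proteomic biomarker panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletpanel)
```

## The problem and the pipeline

Blood platelets share enough biology with neurons that their proteome shifts
with cognitive decline, making them a candidate peripheral matrix for
Alzheimer's-disease screening. `plateletpanel` implements a complete discovery
pipeline for cohorts of the common three-group design — cognitively normal
controls (Ctrl), mild cognitive impairment (MCI) and severe impairment (AD) —
profiled by multiplexed TMT quantitative proteomics, with a per-subject MMSE
score (mini-mental state examination, 0–30, lower = more impaired) as the
clinical anchor:

1. **Preprocess**: per-group quantification filter, log2 + median
   normalization, downshifted-normal imputation.
2. **Differential expression**: per-protein Student t-tests over the three
   group contrasts, raw p < 0.05.
3. **Trajectory clustering**: k-means (k = 3) on standardized group-mean
   triples across Ctrl → MCI → AD.
4. **MMSE correlation**: Pearson r of every protein against MMSE, split into
   negatively/positively correlated (NC/PC) classes.
5. **Candidate set**: proteins that are both differential and MMSE-correlated.
6. **Enrichment** (optional): hypergeometric over-representation against
   user-supplied GMT gene sets.
7. **PLS-DA / VIP**: NIPALS partial least squares discriminant analysis with
   variable-importance-in-projection triage (VIP > 1).
8. **Panel search**: exhaustive leave-one-out evaluation of all candidate
   subsets with a class-balanced ridge logistic classifier, ranked by pooled
   AUCROC.

A synthetic-cohort generator with planted ground truth makes every stage
testable without patient-level data, which for the motivating study design is
not publicly deposited.

## The synthetic cohort: what it emulates

`cohort_design()` defaults state the emulated world explicitly:

* **9 Ctrl / 10 MCI / 9 AD subjects**, MMSE drawn uniformly on the group
  ranges 29–30 / 18–23 / 2–17. Only ranges (and SDs) are published for the
  target cohort; the uniform is the least-assuming integer generator.
* **3,000 quantified proteins**, baseline log2 reporter abundances
  Normal(mean 20, SD 2) per protein — a typical reporter-intensity scale; the
  source study publishes no intensity distribution.
* **360 planted trajectory proteins** in three archetypes (160 monotone-down,
  135 down-then-up, 65 monotone-up across Ctrl → MCI → AD), stepping
  `effect_size` (default 0.8 log2 units) per group transition.
* **A planted true panel** (default 4 proteins, leading the monotone-down
  block): decreased in both impaired groups, the recoverable analog of a real
  biomarker panel.
* **MMSE-correlated proteins** (default 90 positive, 30 negative, roughly the
  published 3:1 PC:NC ratio): a protein gains
  `beta * z(MMSE)` with `beta = noise_sd * r / sqrt(1 - r^2)`, giving expected
  Pearson r equal to `target_corr` (default 0.55, the strongest published
  protein–MMSE correlation) in closed form.
* **Residual noise** `noise_sd = 0.5` log2 units (~41% CV), typical
  inter-subject variation for clinical cohort proteomics. This value also
  reproduces the published discrimination regime — single planted proteins
  reach pooled leave-one-out AUCROC ≈ 0.85–0.93 while multi-protein panels
  approach 0.96+ — rather than a saturated world in which every planted
  protein separates the classes perfectly.
* **Left-censored missingness** (default 5% of cells): cells go missing with
  probability decreasing linearly in their abundance rank, vanishing above
  the bottom quartile. Missing cells therefore really were low — exactly the
  mechanism downshifted-normal imputation assumes. Missingness is *not* a
  group-balanced coin flip: a strongly down-regulated protein can drop below
  detection specifically in the impaired groups, and in unlucky baselines can
  fail the per-group quantification filter altogether, as in real data.

What the generator does **not** emulate: peptide-level quantification and
rollup, TMT ratio compression, batch structure, correlated protein modules
beyond the shared MMSE driver, and covariates (age, sex, APOE). A green
recovery test therefore establishes that the algorithms recover planted
structure of the stated strength under idealized independence — not that the
pipeline is robust to every artifact of real LC-MS/MS data.

## Numerical and design choices

**Normalization.** Columns are log2-transformed and median-centered to the
global median. The platform named by the motivating study ("Perseus")
supports several normalizations; median subtraction is its standard choice
and is idempotent, which the tests exploit.

**Quantification filter.** Proteins observed in < 70% of the samples of any
group are dropped before testing (configurable). The published counts (4,165
identified → 2,994 "effectively captured in each experimental group") imply
such a per-group completeness rule without stating its threshold.

**Imputation.** Missing cells are drawn from
Normal(col\_mean − 1.8 · col\_SD, (0.3 · col\_SD)²) — the downshifted-normal
defaults of the named platform (width 0.3, downshift 1.8). Observed cells are
never modified; a seed makes imputation replayable.

**Differential testing.** Two-sided pooled-variance Student t-test on log2
abundances (the platform's two-sample default; Welch available via
`var_equal = FALSE`). Contrast "X vs Ctrl" is signed as mean(X) − mean(Ctrl).
No multiple-testing correction is applied to the selection rule, mirroring
the published raw p < 0.05; a Benjamini–Hochberg column is emitted for
information only.

**Trajectory clustering.** Only the differential-protein union is clustered
(the published archetype counts sum exactly to the differential total,
implying differential-only clustering). Profiles are group-mean triples
standardized with the population SD; k-means with k = 3 fixed, 20 seeded
starts, inputs sorted by protein id so the result is invariant to input
order. Clusters are *labeled* (not fitted) by centroid shape; if shapes are
ambiguous, nearest-archetype matching applies with a warning. Average-linkage
hierarchical clustering is available as an alternative.

**Correlation inference.** Pearson p-values use the exact t-transform
`t = r sqrt((n-2)/(1-r^2))`, df = n − 2, computed on normalized, imputed
abundances. Candidates are ranked by |r| descending with lexicographic tie
breaks for reproducibility.

**Enrichment.** The background is the quantified-protein universe (standard
ORA practice for proteomics), never the genome. Reporting rule: overlap ≥ 3
and raw p < 0.01.

**PLS-DA and VIP.** X is autoscaled; Y is the centered one-hot three-class
matrix (the published score plot shows all three groups even though the
classifier stage is binary). Components come from NIPALS with deflation,
A = 2 by default. VIP uses the standard formula
`VIP_j = sqrt(P * sum_a(ssy_a w_ja^2) / sum_a(ssy_a))`, whose mean square is
1, so VIP > 1 marks above-average contributors. The original analysis used a
commercial implementation's "VIPpred" (an OPLS notion); standard VIP over all
predictive components is the published-formula approximation, and the
selection rule (VIP > 1, strict) is unchanged.

**Classifier.** The impaired class pools MCI and AD (the published PLS-DA
could not separate MCI from AD). The logistic classifier minimizes a ridge
(λ = 1) penalized, class-weighted log-likelihood with weights
`n/(2 n_c)` ("balanced"); the intercept is unpenalized. Features are
autoscaled with training-fold statistics only, so no information from the
held-out sample leaks into its prediction. A compiled Newton solver mirrors
the reference R implementation exactly and is equivalence-tested against it;
the R solver is itself tested against an independent numerical optimizer.

**Evaluation.** All n held-out probabilities are pooled (with one test
sample per fold, per-fold AUCs do not exist; pooling is the only coherent
reading). Confusion matrices use threshold 0.5 (unstated in the source;
a deliberate default). ROC AUC is the trapezoid over the threshold sweep,
which equals the pairwise-concordance statistic with ties half-credited;
PR AUC uses the non-interpolated step rule. Constant score vectors get
AUC 0.5 with a warning.

**Search.** Exhaustive over all 2^k − 1 candidate subsets (capped at k = 20),
ranked by AUCROC descending, accuracy descending, panel size ascending, then
lexicographic; per-size winners are reported. A greedy forward search (no
size cap, stops when AUCROC stops improving) is the scalable alternative and
can never beat the exhaustive optimum.

## Known limitations

* **Best-panel identity is noisy at n = 28.** The pooled AUC of 28 samples
  has granularity 1/171 and standard error ≈ 0.02, so many strong panels tie
  near the top and the identity of the argmax panel is partly a lottery; the
  size-ascending tie-break then favors small panels. Recovery experiments
  across 50 planted cohorts find the best panel contains ≥ 3 of the 4 planted
  proteins in only ~half of the seeds — at any noise level — although it
  essentially always contains planted signal. The corresponding acceptance
  assertion is kept at its stated ≥ 90% bound and is expected to fail; treat
  the per-size winner table, not the single best panel, as the robust output.
* The median normalization assumes balanced up/down regulation; with planted
  asymmetric regulation the null false-positive rate rises slightly above
  the nominal level in affected cohorts (null cohorts are calibrated at 5%).
* Recovery runs hand the full normalized, imputed matrix to the candidate
  stages: the completeness filter can censor strongly down-regulated planted
  proteins out of the filtered matrix entirely, which is a property of the
  filter, not of the candidate-ranking machinery under test.
* No covariate adjustment, no nested cross-validation, no external
  validation cohort — matching the scope of the motivating analysis.

## A worked run

```{r run, eval = FALSE}
cfg <- pipeline_config(out_dir = tempfile("ppanel"), seed = 1,
                       design = cohort_design(n_proteins = 600,
                                              n_cluster1 = 32, n_cluster2 = 27,
                                              n_cluster3 = 13, n_corr_pos = 18,
                                              n_corr_neg = 6))
res <- run_pipeline(cfg)
res$search$best
res$search$best_evaluation$metrics
```

Every table the pipeline writes is a TSV that round-trips through
`read_tsv()`; `summary.tsv` collects the headline numbers, and rerunning with
the same config and seed reproduces the bundle byte for byte.
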
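---
title: "Methods: a urine DNA methylation biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a urine DNA methylation biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmark)
```

## The scientific setting

Bladder cancer sheds exfoliated cells into urine, and hypermethylated CpG
islands in those cells' DNA can be assayed noninvasively. A biomarker
study of this kind proceeds in three tiers, each with its own measurement
technology and statistics:

1. *Discovery* on a small set of paired primary-tumor / adjacent-nontumor
   tissues using a CpG-island microarray, looking for genes whose probes
   are consistently enriched for methylation in the tumor channel.
2. *Confirmation* by bisulfite-pyrosequencing, which reads out the
   methylated-cytosine fraction at 3–5 individual CpGs per amplicon; the
   gene-level methylation index (MtI) is the arithmetic mean of those
   fractions, on a 0–100 percent scale.
3. *Clinical validation* by quantitative methylation-specific PCR (qMSP)
   on urine sediment DNA from an independent cohort, scored as
   40−ΔCT = 40 − (CT~target~ − CT~reference~) and dichotomized at a fixed
   cutoff, with diagnostic performance and clinicopathological
   associations as the endpoints.

`methmark` implements each tier as an independent module plus simulators
that generate statistically realistic inputs, so the whole pipeline is
exercisable and testable end to end.

## Discovery model

For each probe we observe a methylation-enrichment log~2~ ratio in the
tumor and nontumor channel of each specimen pair. With exactly two paired
conditions, the parametric analysis-of-variance reduces to the two-sided
paired t-test on per-pair differences, which is what `test_probe_paired()`
computes. Raw p values across all reliable probes are corrected by
Benjamini–Hochberg (`benjamini_hochberg()`, delegating to
`stats::p.adjust` after validation); a probe earns a *positive call* when
its adjusted p falls below `alpha` (default 0.01), its linear fold change
`mean(2^tumor)/mean(2^nontumor)` is at least `fc_min` (default 2.0; the
fold-change threshold of such screens is a study choice, so it is a
parameter), and the tumor mean exceeds the nontumor mean (hypermethylation
direction). `select_candidates()` returns genes with at least `min_probes`
(default 2) positive probes — a multi-probe enrichment rule that guards
against single-probe artifacts — ranked by probe support and mean fold
change, ties broken lexicographically for determinism.

Degenerate inputs: identical tumor/nontumor vectors are rejected (no
variance, no information); a constant nonzero difference has infinite
separation and is reported with `raw_p = 0` and an infinite statistic.
"Reliable probe" status is an input mask: array-level QC happens upstream
of this package in feature-extraction software, so the generator marks all
probes reliable by default and real datasets can supply their own mask.

### What the array simulator emulates

`generate_array_dataset()` draws each probe's pair of log-ratios as a
shared per-probe, per-pair component plus independent channel noise. The
shared component (fraction `pair_cor = 0.5` of the marginal variance)
models what the two channels of one patient have in common — probe
affinity, regional background methylation, hybridisation batch — and is
the reason paired designs gain power; marginally each log-ratio has SD
`noise_sd`. Planted genes have **all** their probes shifted upward by
`effect_size` in the tumor channel, since a CpG-island methylation event
affects the whole island that the gene's probes tile; `min_planted_probes`
documents and validates the minimum the downstream gene rule may rely on.
The default design (200 genes × 4 probes, 9 pairs, effect 3·`noise_sd`)
mirrors a small paired discovery experiment. Under these conditions
selection recovers ≥ 95% of planted genes across seeds and selects
essentially no genes under a null (zero-effect) configuration.

What it does *not* emulate: probe-sequence effects, spatial artifacts,
dye bias, or the heavy-tailed noise of real two-color arrays — passing
recovery tests here demonstrates the selection logic, not robustness to
raw-array pathology (which belongs to upstream normalisation software).

## MtI cohorts: truncated-normal moment matching

Published cohort summaries give only mean ± SD of MtI per group, and MtI
is bounded in [0, 100]. The simplest bounded two-parameter family that can
match both moments is a normal truncated to [0, 100]; because truncation
shifts moments, `calibrate_truncnorm()` solves numerically (Nelder–Mead on
the squared moment error, tolerance 1e-4) for the parent (μ, σ) whose
*post-truncation* moments equal the targets. Strongly skewed targets (e.g.
mean 33.6, SD 25.4 near the lower bound) are feasible but map to extreme
parents; an infeasible pair (no truncated normal attains it, e.g. SD 80 on
a 0–100 range) raises a calibration error rather than silently missing the
target. The default calibration table (`mti_calibration_defaults()`) holds
the urine-cohort group summaries for the three pyrosequencing-verified
genes with the verification cohort sizes (12 healthy / 23 benign / 16
cancer).

Each sample draws from its own substream (a seed mixed from the cohort
seed and the sample index), so enlarging a cohort never changes earlier
samples — useful for incremental designs and for reproducibility
invariants. At n = 10⁴ the sample mean sits within 3 standard errors of
the target; that is the generator's calibration contract.

The per-CpG expansion in `simulate_pyro_table()` jitters 3–5 CpG fractions
around the drawn MtI (SD 0.03 on the fraction scale) and recentres when no
clipping occurred, representing within-amplicon CpG heterogeneity. It does
not model bisulfite-conversion failure or pyrogram chemistry; missing CpGs
are simply absent rows, and `compute_mti()` averages whatever CpGs are
present (requiring at least one).

## qMSP scoring conventions

The 40−ΔCT score increases with methylated-template abundance: one cycle
earlier target detection adds one unit. Three conventions are explicit
parameters because published protocols often leave them implicit:

* **Reference gating** — the CpG-free reference amplicon only certifies
  that amplifiable bisulfite-converted DNA is present, so a specimen with
  an undetected or late (`> 38` cycles by default, configurable) reference
  CT is *invalid*, not negative.
* **Imputation** — an undetected target CT in a valid specimen scores the
  floor value 25, chosen just below the lowest observed detected score; the
  floor classifies negative at any realistic cutoff, and with the default
  reference bound no detected CT pair with reference CT ≥ 25 can score
  below it.
* **Strict cutoff** — positive means score *strictly above* the cutoff
  (default 31.35). With continuous scores the choice of strict versus
  non-strict is untestable on real data (cutoffs sit between observed
  scores); it matters only for synthetic edge cases, so it is documented
  and fixed.

Run-level QC (`qc_run()`) demands exactly one fully methylated positive
control (must classify positive), one unmethylated negative control
(undetected target or below-cutoff), and one non-template control (no
amplification in either channel); any failure invalidates the run. Assay
constants (annealing 60 °C, 40 cycles, amplicon +524 to +595 bp) ride
along as immutable metadata (`qmsp_assay_metadata()`) and never enter
computation — the coordinate system of the amplicon annotation is recorded
verbatim only.

The qMSP simulator assigns positivity by a Bernoulli draw per sample, then
constructs CT pairs consistent with the assigned class: positives'
detected target CTs are truncated so the score exceeds the cutoff;
negatives drop out (undetected target) with probability 0.8 — the split
between dropout and low-scoring detection is not identified by published
counts, so it is an arbitrary configurable default — and otherwise score
below the cutoff. Stratum defaults (`qmsp_validation_defaults()`) use only
explicitly published fraction pairs: Ta low-grade 10/18, the combined Ta
high-grade + T1–T4 stratum 32/37, an 8/106 false-positive rate shared by
benign and healthy controls, and zero positivity for other urologic
cancers. Finer per-stage positivities are deliberately not defaulted: the
published per-stage percentages cannot be reconciled with any integer
partition of the combined stratum's 32/37, so only the explicitly printed
count pairs are trusted.

## Diagnostics layer

* **ROC/AUC** (`roc_curve()`): thresholds are midpoints between distinct
  scores plus ∓∞ sentinels; positive means score strictly above threshold.
  AUC is the Mann–Whitney pair-counting statistic (ties count ½), which
  equals trapezoidal integration of the empirical ROC exactly; the test
  suite asserts both equalities against brute-force enumeration. The AUC
  confidence interval is the asymptotic normal over the DeLong placement
  variance — with one score scale and two classes this *is* DeLong's
  estimator, and it is cross-checked against an independent implementation.
  The placement computation is O(n₁·n₀), fine for cohort-scale data.
* **Cutoff selection** (`optimal_cutoff()`): maximum Youden J =
  sensitivity + specificity − 1, the default criterion of standard ROC
  software; ties break toward higher specificity, then the higher
  threshold, so a degenerate all-tied curve returns the all-negative
  sentinel. Equality with exhaustive threshold search is asserted on every
  random instance tested.
* **Exact intervals** (`clopper_pearson()`): beta-quantile exact binomial
  intervals, reported in percent. This method was chosen because the
  reconstructed validation counts (32/37 cases; 98/106 controls) reproduce
  the published interval bounds to one decimal — a verification the test
  suite performs — and its empirical coverage is ≥ 94.5% in simulation.
* **Fisher exact** (`fisher_exact()`): two-sided p as the sum of
  hypergeometric point probabilities not exceeding the observed table's
  (with a 1e-7 relative guard against floating-point ties) — the
  convention that reproduces the published association p values. Zero
  margins yield p = 1 with a warning by convention.
* **Kruskal–Wallis** (`kruskal_wallis()`): rank H with tie correction and
  the χ² reference on k−1 degrees of freedom; when every observation is
  tied the data carry no evidence and H = 0, p = 1.
* **Association tables** (`association_table()`): the standard clinical
  dichotomies — sex, age at 65 (the customary geriatric cut in these
  cohorts), stage Ta–T1 vs muscle-invasive T2–T4, grade low vs high with
  unknown-grade samples excluded. Report rounding follows clinical
  convention: percentages to 1 decimal, p to 3 decimals.

## Deterministic validation fixture

`validation_fixture()` rebuilds the 169-sample validation cohort with
per-sample calls whose margins reproduce the published association counts
exactly (42/55 cancers positive; 32/43 male, 10/12 female; 12/19 under 65,
30/36 at or over; 37/50 Ta–T1, 5/5 T2–T4; 16/26 low grade, 26/28 high
grade, one unknown-grade negative; 10/18 Ta low-grade and 17/19 high-grade
T1 positive; 8/106 control false positives). The published margins do not
jointly constrain attributes across each other, so within each call
stratum sex, age and stage/grade assignments are independent and
deterministic; the 6-healthy/2-benign split of the 8 false positives and
the T2/T3/T4 split of the five muscle-invasive cancers are arbitrary
choices that no published margin distinguishes. This fixture is what lets
the statistics layer be checked against published numbers exactly rather
than in expectation; the stochastic generators are checked in expectation
with seed-fixed draws.

## Orchestration and reproducibility

`run_pipeline()` chains simulate → discover → MtI comparison → qMSP
scoring → validation, writing every intermediate table, a summary and a
parameter log. All randomness derives from one top-level seed through
fixed substream offsets; files are staged and atomically renamed; reports
contain no timestamps — two runs with one seed are byte-identical, and the
suite asserts it. Problem sizes in the default configuration (200-gene
arrays, 51-sample pyrosequencing cohorts, 169-sample validation cohort,
10⁴-draw calibration checks) are chosen to mirror the study designs being
emulated while keeping a full run interactive.

## Known limitations

* The generators model distributional structure (group means/SDs,
  positivity rates, detection dropout), not mechanistic assay physics;
  agreement on synthetic data validates the analysis logic, not wet-lab
  robustness.
* The AUC of the real validation cohort is not reproducible from published
  information (per-sample scores were not released), so ROC correctness is
  established by oracle equivalence and simulation rather than by matching
  a published AUC; the same holds for the cutoff value 31.35 itself, which
  is carried as the default operating point rather than re-derived.
* Stage-resolved sensitivities beyond the explicitly published count pairs
  are intentionally unmodelled (see above).
* `fisher_exact()` and `kruskal_wallis()` target 2×2 and k-group one-way
  layouts respectively; no stratified or multivariable modelling is
  provided.
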
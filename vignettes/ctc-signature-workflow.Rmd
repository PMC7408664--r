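---
title: "Deriving and validating a CTC-specific expression signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a CTC-specific expression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcsig)
```

## The problem

Circulating tumor cells (CTCs) enriched from peripheral blood by
EpCAM-based immunocapture are never pure: the captured fraction is
dominated by non-specifically isolated blood cells, mainly lymphocytes.
Any expression profile measured on such a fraction is therefore a mixture
of tumor signal and blood background. This package implements the
two-arm analysis that deals with that mixture:

1. **Discovery arm.** Expression arrays are run on the CTC-enriched
   fraction of a small patient cohort *and* on healthy donors processed
   identically. The healthy arrays estimate the background of unspecific
   capture; genes detected in the healthy background are discarded, and
   the CTC signature is the set of remaining genes detected in at least
   *k* patients (default 5 of 9).
2. **Validation arm.** Candidate markers are re-measured by qPCR in a
   larger cohort (default 28 patients vs 15 controls). Expression is
   scored on the 40−Ct scale normalized against CD45 — a pan-leukocyte
   marker that quantifies the amount of contaminating blood cells per
   sample — and compared between groups by rank tests with FDR control,
   a combined logistic panel ROC, and marker-dichotomized survival
   analysis.

Every stage is driven by synthetic cohorts with emitted ground truth, so
recovery of the signature and the calibration of every test can be
checked end to end.

## Discovery arm

### Spot filtering and detection calls

Arrays arrive as spot-level tables in an Agilent Feature Extraction
dialect (`read_spot_table()`, column mapping configurable via
`agilent_dialect()`). The processed signal is used throughout, rather
than the background-subtracted signal, because it is the more stable
quantity for downstream statistics. Three quality criteria are applied
per array (`qc_filter_spots()`):

* **(a)** spots flagged as non-uniform or population-replicate outliers;
* **(b)** spots not distinguishable from their own background, taken
  from the upstream above-background flag — the per-spot background test
  belongs to the image-analysis software that produced the files, and
  the synthetic generator sets the flag from its own noise model;
* **(c)** spots in the range of the negative controls, operationalized
  as signal ≤ mean + *k*·SD of the array's negative-control signals.
  The published description says only "in the range of the negative
  controls"; mean + 3 SD is the conventional reading and *k* is a
  policy parameter (`filter_policy(negcontrol_k = )`). The threshold is
  computed over all negative-control spots of the array, before any
  spot removal, so it is a deterministic property of the array.

A spot failing several criteria is attributed to the first failing one
(order a, b, c), so per-criterion counts plus removed control spots sum
exactly to the filtered total. A **detection call**
(`detection_call()`) is the conjunction: above background, above the
negative-control threshold, and not outlier-flagged.

### Normalization and the common-probe question

Filtering and detection are defined on raw signals; intensities are then
log2-transformed and quantile-normalized across arrays
(`quantile_normalize()`, the limma implementation with mean-of-ties
handling), forcing identical empirical intensity distributions while
preserving within-array ranks.

One design question is genuinely open: which probes enter
normalization? A strict policy — drop from every array any probe
filtered in *any* array — sounds conservative but has a fatal
interaction with this study design: a CTC-specific gene is, by
construction, absent (criterion b/c) in every healthy array, so the
strict policy deletes exactly the probes the signature is made of. The
default (`probe_policy = "all_experimental"`) therefore normalizes all
experimental probes — the probe index is identical across arrays of one
platform, so equal-length vectors are guaranteed — and lets absence
calls mark a probe undetected without discarding its measured intensity.
The strict variant remains available as
`probe_policy = "common_retained"` for platforms where probe sets
genuinely differ in reliability, and the test suite demonstrates that it
removes the spiked genes from the matrix.

Replicate probes are collapsed to genes by the median of their
normalized intensities, with an any-probe-detected rule for the gene
detection call; the median resists single-probe artifacts, and the
any-rule matches "present" being a detection statement, not an
intensity statement. Presence for the signature rule is evaluated at
gene level, after collapse; this is configurable in the sense that the
probe-level detection matrix is also returned by the pipeline.

### Signature selection

`select_ctc_genes()` applies the k-of-n rule on the detection-call
matrix: healthy count ≤ `max_healthy_count` (default 0) and patient
count ≥ `min_patient_count` (default 5). "Expressed in healthy
samples" is read strictly — a single healthy detection excludes a gene —
and the parameter exposes that reading. Selection never looks at
intensities; the filter criteria define detectability, and intensities
matter only downstream. Selection is monotone under rule relaxation,
and on synthetic cohorts it must coincide exactly with brute-force set
logic over the detection counts.

## The synthetic array generator

`simulate_array_cohort()` emulates the discovery design: 9 patient and
6 healthy arrays, 2,000 gene units × 2 probes, 100 negative controls.
Background genes are log-normal on the log2 scale
(mean 8, SD 1 in log2 units — a mid-range intensity typical of
expression arrays); negative controls and absent genes sit on a noise
floor (log2 mean 4, SD 0.5); a detectable CTC-gene spot sits
`signal_shift` (default 6 SD) above background; 40 spiked CTC genes are
each detectable in a given patient array with probability 0.7; and 2%
of spots carry an outlier flag. Ground truth (which arrays carry which
spiked gene) is emitted alongside and never consumed by the pipeline.

What the generator does **not** model: capture-chemistry and
amplification biases, dye effects, spatial artifacts, and correlated
expression between genes. Passing recovery tests therefore show the
pipeline's logic is correct under the stated signal/noise geometry, not
that real arrays meet that geometry.

Two consequences of the noise model are worth stating. First, with a
6 SD spike margin the detection threshold sits far from both the floor
and the spike, so detection errors come only from outlier flags: a
carried gene-array occurrence is lost only when *both* replicate probes
are flagged (probability `outlier_rate²` ≈ 4·10⁻⁴ at the default 2%).
Second, that rare loss matters only for genes whose true patient
occupancy is exactly at the selection boundary (5 of 9); across seeds
one sees occasional single-gene misses of this kind, which is the
designed behavior of filtering under outlier contamination, not a
pipeline defect — the analysis scripts report the ground-truth overlap
so this is visible.

## Validation arm

### Scoring

`normalize_ct()` averages duplicate wells, then scores each gene as
`(40 − Ct_gene) − (40 − Ct_CD45)`. The direction of the subtraction is
chosen so that higher score = higher expression relative to the
lymphocyte background, the orientation under which "high marker, worse
outcome" statements read naturally. Undetected wells are imputed at the
cycle floor (default 40) by the generator, the standard qPCR floor
convention, keeping scores finite; samples missing a gene entirely
propagate as missing, never as zero. The 1:10 dilution and 14×
pre-amplification of the wet-lab protocol are bookkeeping upstream of
the Ct values and receive no computational correction.

### Tests

* `mannwhitney_test()` — two-tailed Mann–Whitney U. Exact p-values (by
  the null permutation distribution of U) for tie-free data with
  min(n) ≤ 8, where enumeration is cheap; otherwise the normal
  approximation with tie-corrected variance and continuity correction.
  Two identical constant groups return p = 1 rather than an error.
* `bh_fdr()` — Benjamini–Hochberg step-up, the default meaning of
  "FDR adjustment" when no variant is named.
* `roc_auc()` — empirical ROC with DeLong confidence interval; the AUC
  is algebraically U/(n₁·n₂) and the test suite holds the two code
  paths to that identity at 10⁻¹².
* `fit_panel_logistic()` — a binomial-logit model combining the marker
  scores; the model family behind a published "regression model" ROC is
  rarely stated, and the logit is the canonical binary-outcome choice.
  Perfect separation is flagged rather than hidden; the panel ROC of
  the linear predictor remains valid in that case.
* `pearson_corr()` — two-sided product-moment correlation for clinical
  covariates.

### qPCR generator and calibration

`simulate_qpcr_cohort()` draws a latent score per sample and gene
(control baseline + effect for patients) and produces duplicate wells
with `ct_sigma` (default 1 cycle) replicate noise around
`Ct_CD45 − score`. Default effects are 2 score units on all six panel
markers, and the control baselines are placed so the published fixed
cut-offs (−3.8, −4.1, 0.4, −4.0, 0.5, −2.0 for HOXB13, MAOA, FGD4,
MOSPD1, QKI, SDK1) fall midway between the group means. Between-sample
biological variance beyond the group shift is deliberately zero: the
score SD then equals `ct_sigma` (duplicates of gene and reference each
contribute half), which is the regime in which the documented power and
calibration properties are stated. Real cohorts have heavier
inter-patient dispersion; the dichotomized survival analyses are the
part of the workflow designed for that.

With effects set to zero the whole chain (generator → scoring → test)
must reject at the nominal rate; the acceptance tests run 2,000 null
cohorts at the design sizes (28 vs 15) and require the per-marker
rejection rate at α = 0.05 to land in [0.04, 0.06], and 1,000 null
survival cohorts with log-rank rejection in [0.03, 0.07].

## Survival arm

`km_estimate()` wraps the product-limit estimator with Greenwood
variance. Published marker-survival tables report a "mean" per group;
this is interpreted as the **restricted mean** — the area under the KM
curve up to the largest observed time of that group — the convention of
mainstream clinical-statistics software, since an unrestricted mean is
undefined under censoring. The test suite checks the restricted mean
against an independently hand-rolled step-area oracle at 10⁻¹². At tied
times events precede censorings. All times are months; no date parsing.

`logrank_test()` and `cox_fit()` wrap the standard log-rank statistic
and Cox partial-likelihood fit (Breslow tie handling by default, Efron
available). Monotone likelihood (separation in time order) is flagged
with coefficients reported at the iteration cap. A covariate with no
contrast is reported as coefficient 0 / HR 1 rather than `NA`, so
degenerate dichotomizations stay interpretable. The score test of a
two-group Cox fit equals the log-rank chi-square on tie-free data; the
suite asserts the equivalence at 10⁻⁶.

`marker_survival_report()` ties the arms together: dichotomize each
marker (median, nearest-rank 70th percentile, or fixed published cuts),
KM restricted mean ± 95% CI per group, log-rank p — one low/high row
pair per marker. P-values are reported unadjusted, as marker-survival
tables conventionally cite the log-rank test directly. Which markers
used median vs percentile-70 cuts in the published analysis is not
stated per marker, so the fixed cut-offs from the table footnote are
used for reproduction runs. `simulate_survival()` generates exponential
event times with log-hazard linear in the (cohort-centered) marker
scores and independent uniform censoring; centering keeps the baseline
hazard (default median 8 months at zero log-hazard, a realistic
progression timescale for this disease setting) interpretable
regardless of the score origin.

## Numerical choices

* Detection thresholds and filtering operate on raw (linear) signals;
  log2 is applied after filtering, before normalization.
* Quantile-normalization ties receive the mean of their tied-rank
  substitutes; sorted columns agree to 10⁻⁹ afterwards.
* Nearest-rank percentile (`sorted[ceiling(p·n)]`) for the 70% cut:
  deterministic and software-independent, documented so interpolating
  definitions can be compared.
* Exact Mann–Whitney enumeration is bounded to min(n) ≤ 8 to keep the
  exact path cheap; the identity p ∈ [0, 1] and q ≥ p are enforced.
* Logistic IRLS: relative deviance tolerance 10⁻⁸, 100 iterations;
  Cox Newton–Raphson: 50 iterations.
* `dichotomize()` labels `low` as score ≤ cut; a cut that leaves one
  side empty warns (data-driven) or is skipped with a warning
  (survival report).

## Problem sizes used in checks

The shipped tests and acceptance script use the study's own design
scale: 9 + 6 arrays × 4,100 spots for discovery recovery, 28 vs 15
qPCR samples, 2,000 null cohorts for rank-test calibration, 1,000 for
log-rank calibration, n = 500 for Cox parameter recovery, and n = 2,000
(× 10 replicate cohorts, judged on the mean estimate) for logistic
coefficient recovery. These sizes keep every property estimable with
comfortable Monte Carlo error while completing in minutes on one core.

## Known limitations

* The generators draw genes independently; co-expression structure,
  batch effects and amplification bias are not modeled.
* Criterion (b) trusts the upstream above-background flag; arrays whose
  feature-extraction software uses a different background test will
  shift the filter counts.
* The strict common-probe policy is incompatible with signatures
  defined by group-specific absence (see above) and is therefore not
  the default.
* Restricted means for very small dichotomized groups carry wide
  normal-theory intervals (occasionally crossing zero); with a handful
  of subjects per group that is a faithful statement of uncertainty,
  not a bug.
* Real discovery cohorts (deposited as GEO series GSE153514) can be
  analyzed by pointing `run_discovery()` at the per-sample spot tables
  with an appropriate dialect mapping; the package performs no
  downloading.
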
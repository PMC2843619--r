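---
title: "Quantifying and correcting intra-experiment batch effects in BeadChip data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and correcting intra-experiment batch effects in BeadChip data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipbatch)
```

## The problem

Multi-array expression chips are typically hybridised and scanned in several
processing runs spread over days. Even within a single laboratory, a single
protocol and a single platform, each run imprints a systematic bias — a
*batch effect* — on the measured intensities. When each biological sample is
hybridised once (the norm, given cost and RNA scarcity), this technical
variation is confounded with the biology and can dominate the lists of
differentially expressed genes an experiment reports.

`chipbatch` packages the analysis machinery needed to *measure* that
intra-experiment variation and to *remove* it: detection filtering,
normalisation, two batch-correction methods, per-gene variance
decomposition, technical-replicate diagnostics, and a duplicate-split
differential-expression (DE) consistency score that quantifies how
reproducible a gene list actually is. A synthetic-data generator emulates
the reference-anchored hybridisation design these experiments use, so every
stage is testable end to end.

## The variance model

For one gene, let $X_{ij}$ be the log2 expression of the $j$-th replicate
array in run $i$. The nested (one-way random effects) model is

$$X_{ij} = \mu + A_i + \varepsilon_{ij}, \qquad
A_i \sim N(0, \sigma^2_A), \quad \varepsilon_{ij} \sim N(0, \sigma^2),$$

so the variance of any observation is $\sigma^2_A + \sigma^2$: the
inter-batch and intra-batch components. `nested_anova()` estimates both per
gene by the method of moments for the unbalanced design with $b$ batches of
sizes $n_i$, $N = \sum n_i$:

$$\hat\sigma^2 = MS_W = \frac{SS_W}{N-b}, \qquad
\hat\sigma^2_A = \max\!\left(0, \frac{MS_B - MS_W}{n_0}\right), \qquad
n_0 = \frac{N - \sum n_i^2 / N}{b - 1}.$$

Negative moment estimates of $\sigma^2_A$ are truncated to zero and
flagged — after an effective correction the between-run component is
typically no longer detectable, so a large truncated fraction is the
expected signature of success. Because diagnostic plots in this field show
standard deviations, the between-run *share* is reported on the SD scale,
$s_A / (s_A + s)$, alongside the variance-scale share.

## Corrections

**Mean-centring** (`mean_center()`) shifts, per gene, each batch onto the
gene's grand mean. It removes additive location effects exactly: after
correction every batch mean equals the grand mean to numerical precision.
Without covariates the batch means absorb whatever biology is unevenly
distributed across batches; a covariate-protected variant (additive
least-squares fit with a sum-to-zero batch factor) is available.

**Empirical-Bayes location/scale correction** (`eb_batch_correct()`)
assumes each (batch, gene) cell carries an additive location effect
$\gamma_{ig}$ *and* a multiplicative scale effect $\delta_{ig}$ on the
standardised residuals. Per gene the data are standardised against a
least-squares fit (batch means constrained to average out, optional
protected covariates, pooled variance); raw per-batch locations and scales
are then shrunk toward batch-level priors — Normal for locations,
inverse-gamma for scales, both estimated by method of moments across genes —
through coupled posterior updates iterated to convergence. The adjusted
residuals are rescaled and the fitted means restored.

Numerical choices, all deterministic:

* convergence tolerance `1e-4` on the maximum absolute change of the shrunk
  parameters; `max_iter = 1000` because small batches (2 chips) are
  prior-dominated and converge linearly, needing roughly a hundred updates;
* method-of-moments prior variances that come out non-positive (degenerate
  small-gene-count or constant-data cases) are floored at `1e-8` with a
  warning, and an uninformative scale prior (posterior = MLE) is used when
  the scale moments are unusable — so constant genes are corrected onto
  their grand mean rather than crashing on a division by zero;
* shrunk squared scales are floored at `1e-8`.

In the pipeline the EB correction protects the pre/post condition as a
covariate — the standard usage of this correction family — whereas
mean-centring is applied in its plain, covariate-free form, which is how
that simpler method is defined and commonly used. This asymmetry is real
and intentional: it is precisely why mean-centring distorts the treatment
contrast when conditions are unevenly spread over runs, while the EB
correction does not.

**Calibrator mode** (`apply_correction_with_calibrator()`) pools the
reference arrays (one identical technical-reference RNA per chip) with the
study samples, runs the correction with the sample group
(reference / study-pre / study-post) as a protected factor, and returns the
corrected study sub-matrix. Reference-only batches are rejected in the
mean-centring path because their batch means would be estimated from
samples that never enter the result.

## Preprocessing

* **Detection filter**: a probe is removed iff its detection confidence is
  $\le$ 0.80 in *more than* 25% of samples (both boundaries exactly as
  stated; a probe failing in exactly a quarter of the samples is kept).
  Detection values are normalised to confidences at the I/O boundary
  (`1 - p` for p-value exports) so this rule is uniform. Filtering runs
  before normalisation, and each analysis group is filtered independently
  on its own samples.
* **Log2 transform** with floor 1.0; base 2 makes fold-change thresholds
  direct.
* **Quantile normalisation**: classical rank-mean algorithm. Ties within a
  column receive the average of the reference values over the tied rank
  range — deterministic and symmetric. The operation is idempotent and
  leaves every column with an identical sorted value multiset.
* **Median normalisation** is included as the simple comparator: columns
  are shifted so each median equals the grand median of column medians.

Default stage order: filter → log2 → quantile → batch-correct. Reference
and study samples are normalised separately unless the calibrator is in
use.

## Duplicate-split DE consistency

When every study sample is hybridised twice (duplicates *a* and *b* on
disjoint chips), the two replicate sets form independent experiments.
`split_duplicates()` builds groups A (all *a*), B (all *b*) and pooled C;
each retains complete pre/post subject pairs only. Each group is
independently filtered, normalised and corrected, then tested:

* `moderated_paired_t()` — an empirical-Bayes moderated one-sample t on
  paired differences. The prior df $d_0$ and prior variance $s_0^2$ are
  estimated by moment-matching the marginal distribution of $\log s^2$ via
  digamma/trigamma inversion; the posterior variance
  $(d_0 s_0^2 + (n-1)s^2)/(d_0+n-1)$ feeds a t statistic on $d_0+n-1$ df
  with BH adjustment. Forcing `prior_df = 0` recovers the textbook paired
  t exactly.
* `sam_paired()` — a regularised statistic $d = m/(se + s_0)$ with the
  fudge factor $s_0$ = median standard error, and a sign-flip permutation
  null (exhaustive $2^n$ for $n \le 10$): per gene,
  $q = \hat\pi_0\,\mathrm{med}_\pi \#\{|d^*|\ge|d|\} / \#\{|d'|\ge|d|\}$,
  monotonised to be non-increasing in $|d|$ and capped at 1, with
  $\hat\pi_0 = \min(1,\, 2\,\overline{\mathbf 1[p > 0.5]})$ from the
  moderated-t pass. $s_0$ is held at its observed value across
  permutations so a run is reproducible from its seed.

Gene lists use inclusive thresholds (minimum fold change 1.5, maximum
BH-adjusted p 0.01, or maximum q 0.05). The consensus between two lists is
the Jaccard percentage $100\,|A\cap B|/|A\cup B|$, rounded *half-up* to one
decimal (base R's `round()` is round-half-even, which disagrees with how
such tables are conventionally printed). Two empty lists report 0.0 with a
flag.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: 18 chips × 8
arrays in 5 runs of 4/4/4/4/2 chips; slot 1 of every chip carries the
technical reference; the 126 study slots hold 63 duplicate a/b biopsies, of
which 7 have both replicates in the last run and 56 straddle runs, and a
third of the biopsies form complete pre/post subject pairs (21 subjects per
duplicate group). These placements reproduce the replicate-pair census of
the design: 25 intra-run and 128 inter-run reference pairs, 7 intra-run and
56 inter-run duplicate pairs.

On the log2 scale, gene $g$ on array $j$ in batch $i$ is

$$y = \mu_g + \tau_g\,\mathbf 1[\text{post} \wedge g \in DE]
      + \gamma_{ig} + \delta_{ig}\,\varepsilon_{j},$$

with $\gamma_{ig} \sim N(0, 0.22^2)$, $\log\delta_{ig} \sim N(0, 0.1^2)$,
$\varepsilon \sim N(0, 0.18^2)$, $|\tau_g| = 0.8$ on a 5% subset of genes
with random sign. The batch-effect and noise SDs are chosen so the
between-run share of the total SD is near 60% and the total per-gene SD
near 0.28, the regime reported for this class of experiment; setting
`delta_scale_sd = 0` recovers the purely additive variance model.
Emitted intensities are $2^y$; detection confidence is logistic in $y$
(midpoint 6, scale 0.5 — with baselines $N(8, 2^2)$ this filters roughly a
quarter of probes, preferentially the dim ones). Identical configs produce
bit-identical output.

Two layout choices were genuinely open and are fixed as follows:

* **Duplicate placement.** The exact chip-to-run assignment of the original
  design is not recoverable; the default fixes one concrete assignment
  satisfying every published pair count, with the a-replicates on the first
  half of the non-final chips and b-replicates on the second half
  ("completely separate chips").
* **Condition-run imbalance.** Within each duplicate chip set, two of every
  three subjects have their pre biopsy in the earlier chip half and their
  post biopsy in the later half; the third subject is reversed. This
  emulates the partial chronological confounding of clinical sample flows
  (biopsies tend to be processed in collection order) without fully
  confounding treatment with run. Full confounding would make mean-centring
  annihilate the treatment signal outright (its batch means then absorb the
  entire contrast); full balance would make paired tests immune to additive
  batch effects and all corrections indistinguishable. The 2:1 ratio keeps
  mean-centring's attenuation of the planted effect (factor
  $\approx 0.89$) clear of the fold-change threshold while leaving the
  uncorrected analysis visibly batch-sensitive, which is the regime the
  method comparison is about.

Not modelled: subject-level biological variance (paired tests cancel it),
bead-level structure within probes, spatial chip artefacts, and a spectrum
of effect sizes — planted effects are $\pm 0.8$ throughout. The last point
matters for interpretation: with $n = 21$ pairs and technical noise 0.18,
the tests detect essentially every retained planted gene after an effective
correction, so corrected-data recall differences between groups reduce to
detection-filter noise. The benefit of pooling duplicates (group C) into
one analysis is therefore visible where variance is still uncorrected —
on quantile-normalised data C recovers more planted genes than either group
alone — and that is where the package's tests evaluate it. Real data, with
most true effects near the reporting threshold, show the pooling benefit
after correction too.

## Problem sizes used by the test-suite

The suite exercises the full workflow on simulated experiments of 1,500–
2,000 genes (5–10 seeds per property) and the statistical calibration
checks on 400–2,000 genes at 21 pairs; a complete default pipeline run
(12 analysis rows) takes about two seconds. These sizes give Monte-Carlo
error comfortably inside the asserted tolerances while keeping a full test
run under a minute of compute.

## Known limitations

* The EB correction implements the parametric prior form only.
* "Batch" is a single factor (the run); nested or crossed technical factors
  (chip within run, array position) are not decomposed separately.
* The consensus score compares probe-id sets; it does not weight by effect
  size or rank agreement.
* With a single gene (or constant data) the prior moments are degenerate;
  the floors described above make these cases exact rather than estimated.
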
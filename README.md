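# chipbatch

Batch-effect assessment and correction for multi-array expression
BeadChip experiments.

Expression chips are processed in runs — sets of chips hybridised and
scanned together — and each run imprints a systematic technical bias on the
measured intensities. When every biological sample is hybridised once, that
bias is confounded with the biology and can dominate the reported lists of
differentially expressed genes, even within a single laboratory using a
single protocol. `chipbatch` is for analysts of such designs: it quantifies
the intra-experiment technical variation using the technical replicates the
design provides (a reference RNA on every chip, duplicate hybridisations of
study samples), removes the run effects, and scores how reproducible the
resulting gene lists are.

## What it computes

**Variance decomposition.** Per gene, the nested random-effects model
`X_ij = mu + A_i + eps_ij` splits the variance of a replicate measurement
into an inter-batch component `sigma2_A` and an intra-batch component
`sigma2`, estimated by the method of moments for unbalanced designs
(`nested_anova()`), with replicate correlation, replicate-difference,
coefficient-of-variation and detection-consistency diagnostics alongside.

**Corrections.** `mean_center()` shifts each batch onto the per-gene grand
mean; `eb_batch_correct()` is a parametric empirical-Bayes location/scale
adjustment — per-(batch, gene) additive shifts and multiplicative scale
effects are shrunk toward batch-level priors and removed, with optional
protected covariates and a reference-RNA calibrator mode
(`apply_correction_with_calibrator()`).

**DE consistency.** Duplicate hybridisations are split into independent
groups A and B (`split_duplicates()`), each analysed with a moderated
paired t-test (`moderated_paired_t()`) or a SAM-style sign-flip permutation
test (`sam_paired()`), and the thresholded lists are compared by the
consensus percentage `100 * |A ∩ B| / |A ∪ B|` (`consensus()`), the
machine-readable form of a duplicate-experiment summary table.

**Simulation.** `simulate_experiment()` generates the full design — 18
chips x 8 arrays in 5 runs, one reference array per chip, 63 duplicate
pre/post tumour biopsies — with planted batch and treatment effects, so the
whole pipeline is testable without any downloads.

## Worked example

```r
library(chipbatch)

sim <- simulate_experiment(sim_config(n_genes = 2000, seed = 42))
sim$expr
#> <expr_matrix> 2000 probes x 144 samples, scale = linear, detection = present

# variance components of the 18 reference arrays, before correction
vc <- nested_anova(log2_transform(sim$expr), sim$plan, role = "reference")
variance_summary(vc)
#>   mean_sd_between mean_sd_within mean_between_share_sd mean_between_share_var
#> 1           0.201          0.179                   0.5                  0.521

# full workflow: filter -> log2 -> quantile -> correct -> paired DE -> consensus
cfg <- pipeline_config(sim = sim_config(n_genes = 2000), seed = 42,
                       methods = "moderated_t", calibrator = FALSE)
res <- run_pipeline(cfg)
res$report
#>        method calibrator correction n_a n_b n_overlap consensus
#> 1 moderated_t      FALSE         QN  68  70        67      94.4
#> 2 moderated_t      FALSE         MC  70  71        70      98.6
#> 3 moderated_t      FALSE         CB  70  71        70      98.6
res$varcomp[, 1:3]
#>   correction mean_sd_between mean_sd_within
#> 1         QN        0.194816           0.177
#> 2         MC        0.000000           0.177
#> 3         CB        0.000123           0.149
```

Reading the output: the simulated references carry a between-run SD of
about 0.2 against a within-run SD of 0.18 — half the technical SD is
run-to-run (`mean_between_share_sd` 0.50). Both corrections remove the
between-run component entirely (`mean_sd_between` drops to ~0), and the
EB correction also trims the within-run scale. Downstream, the consensus
between the duplicate groups' gene lists rises from 94.4% on
quantile-normalised data to 98.6% after correction; with stronger planted
batch effects or less balanced layouts the spread between the corrections
widens (the methods vignette discusses the regimes).

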
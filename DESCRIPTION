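Package: chipbatch
Title: Batch-Effect Assessment and Correction for Multi-Array Expression BeadChips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and remove intra-experiment batch (run) effects in
    multi-array expression BeadChip studies. Implements detection-confidence
    filtering, quantile and median normalisation, mean-centring and parametric
    empirical-Bayes location/scale batch correction, per-gene nested ANOVA
    variance decomposition, technical-replicate diagnostics (pairwise
    correlation, replicate-difference distributions, coefficient of variation,
    detection-call consistency), and duplicate-split differential-expression
    consistency scoring with a moderated paired t-test and a SAM-style
    sign-flip permutation FDR. Includes a synthetic-data generator that
    emulates a reference-anchored BeadChip hybridisation design with planted
    batch and treatment effects, and a pipeline driver that runs the full
    workflow from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, limma, sva, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
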
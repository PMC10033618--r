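Package: polystage
Title: Fully Efficient Two-Stage Genomic Prediction for Polyploids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage analysis of multi-environment (and multi-trait) plant
    breeding trials for genomic selection.  Stage 1 estimates genotype means
    (BLUEs) and their full variance-covariance matrix per environment; Stage 2
    fits a genomic mixed model that carries the Stage 1 estimation errors as a
    random effect with known covariance, so no information is lost between
    stages.  Supports directional dominance and genomic inbreeding for any
    even ploidy, genomic/pedigree/blended (H) relationship matrices,
    factor-analytic genotype-by-location models, proportion-of-variance
    accounting, BLUP with reliability for additive, breeding, or total genetic
    value, restricted multi-trait selection indices via exact convex
    optimization, and two-stage GWAS by backsolving marker effects.  A
    synthetic-data generator reproduces the distributional assumptions of the
    pipeline for testing and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, lme4
Config/testthat/edition: 3
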
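Package: brainvar
Title: Sex Differences in Developmental Brain Gene Expression Variability
Version: 1.0.0
Author: Package Author
Maintainer: Package Author <maintainer@example.com>
Description: Donor-aware resampling analysis of between-subject gene expression
    similarity in the developing human brain. Implements quality filtering,
    normalization, surrogate-variable estimation and covariate residualization
    for BrainSpan-style cohorts; a three-stage bootstrap estimator of per-sex
    expression similarity across brain regional clusters and overlapping
    developmental age-bins, with donor-level sex-permutation significance and
    Bonferroni correction; identification of "variability genes" by the
    male/female ratio of resample-averaged expression standard deviations;
    co-expression of variability genes with GWAS risk-gene sets against
    variance-matched empirical nulls with family-wise error control; closest
    gene-per-locus risk-gene selection with MHC exclusion; sliding age-window
    fine-mapping; and a synthetic cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
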
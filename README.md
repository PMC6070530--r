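# brainvar

Sex differences in gene expression variability in the developing human
brain, analyzed with donor-aware resampling.

## The problem

Post-mortem developmental brain cohorts (BrainSpan-style) sample many brain
regions per donor across ages from 6 post-conceptional weeks to 40 years.
`brainvar` asks, per brain regional cluster and overlapping developmental
age-bin, whether male donors show lower between-subject **expression
similarity** than female donors; which genes drive such differences; and
whether those genes are co-expressed with schizophrenia GWAS risk genes in
males. It is aimed at analysts working with repeated-measure bulk
transcriptomes where naive pooling of samples would be confounded by
within-donor correlation and unequal group sizes.

## The statistic

For a stratum (one of 4 regional clusters x 11 age-bins built from 13
periods joined 3 at a time), expression similarity for sex *s* is

> S_s = E[ mean of the upper triangle of cor(X_sel) ]

estimated over 100 three-stage resamples: (1) one sample per donor,
uniformly; (2) a donor bootstrap reduced to its unique set; (3) the larger
sex subsampled to the smaller sex's donor count. The cluster-level
difference D = mean over bins of (S_F − S_M) is tested by permuting donor
sex labels within each stratum (1000 permutations, two-sided via |D|,
Bonferroni over clusters).

"Variability genes" are the 100 genes with the highest male/female ratio of
resample-averaged expression SD. Their co-expression with the risk-gene set
(one closest gene per GWAS locus, MHC excluded) is the median of all
between-set Pearson correlations across male subjects, tested against 1000
random gene sets matched within 5% on expression SD and corrected for the
22 variability-gene sets tested (FWER).

A synthetic-cohort generator (`simulate_study()`) with known ground truth
— planted male variance inflation, a latent variability-risk factor,
regional signatures, covariates, batches, replicates — backs the entire
test suite.

## Worked example

```r
library(brainvar)

params <- simulation_params(
  n_genes = 2000, periods = 1:5, donors_per_period = 2,
  regions = c("M1C", "S1C", "VFC", "MFC", "DFC", "OFC",
              "STR", "HIP", "AMY"),
  lambda = 2, rho_star = 0.3)          # male SD x2 in 10% of genes
sim <- simulate_study(params, seed = 1)

cfg <- analysis_config(n_point_resamples = 50, n_null_resamples = 200,
                       n_null_inner = 20, n_null_inner_coexpr = 5,
                       surrogate_count = 0, mhc_region = sim$mhc_region)
pp <- preprocess_pipeline(sim$dataset, cfg, platform = "microarray")
pp$dataset
#> <expression_dataset> 1900 genes x 180 samples (20 donors; 90 M / 90 F samples)
#>   scale: residual
#>   transforms: filter_rin:donor_fraction -> log2_transform ->
#>     filter_age_and_autosomes -> quantile_normalize -> collapse_replicates ->
#>     impute_ph -> residualize -> detect_outliers

strata <- build_strata(pp$dataset, cfg = cfg)
cl2 <- Filter(function(s) s$cluster_id == 2 && s$bin_index <= 3, strata)
sex_difference_test(2, pp$dataset, cl2, cfg, seed = 1)[
  c("mean_difference", "empirical_p", "corrected_p")]
#> $mean_difference
#> [1] 0.04019126
#> $empirical_p
#> [1] 0.01
#> $corrected_p
#> [1] 0.04

st  <- cl2[[2]]
sds <- resampled_gene_sd_pair(st, pp$dataset, cfg, seed = 2)
vg  <- select_variability_genes(sds$male, sds$female, cfg)
mean(vg$gene_id %in% sim$truth$variability_genes)   # recall of planted genes
#> [1] 0.96

rs <- select_risk_genes(sim$loci, sim$annotation, cfg)
cx <- coexpression_test(st, pp$dataset, vg, rs, sds$male, cfg, seed = 3)
c(rho = cx$rho, p = cx$empirical_p, p_fwer = cx$corrected_p)
#>        rho          p     p_fwer
#> 0.08236484 0.02000000 0.44000000
```

The positive `mean_difference` (0.040) says male between-subject similarity
in the prefrontal/motor-somatosensory cluster is lower than female
similarity; only 1% of donor-level sex permutations reach it (corrected
0.04 over the 4 clusters). The selected variability genes recover 96% of
the genes with planted variance inflation, and their median
cross-correlation with the recovered risk set (rho = 0.082 for this seed's
realized factor) is exceeded by 2% of the variance-matched null sets
(FWER-corrected p = 0.44 over 22 tests — single-stratum co-expression at
this cohort size is suggestive, not conclusive, exactly as in small real
strata).

## Layout

| Path | Contents |
|---|---|
| `R/ages.R`, `R/dataset.R`, `R/io.R`, `R/config.R` | domain types, readers/writers, configuration |
| `R/preprocess.R` | filters, normalization, surrogate variables, residualization, outliers |
| `R/resample.R`, `R/similarity.R` | three-stage resampling, similarity estimator, permutation test |
| `R/variability.R` | SD-ratio gene selection, variance-matched nulls, transfer test |
| `R/coexpression.R`, `R/windows.R` | risk-gene selection, co-expression test, specificity sets, age windows |
| `R/simulate.R` | synthetic cohort/genome/expression generator |
| `vignettes/brainvar-methods.Rmd` | the methods vignette: model, assumptions, design choices |
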
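---
title: "Methods: donor-aware analysis of sex differences in brain expression variability"
author: "brainvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: donor-aware analysis of sex differences in brain expression variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Developmental brain cohorts such as BrainSpan sample many brain regions from
each post-mortem donor, spanning ages from the 6th post-conceptional week to
40 years. The question this package addresses is whether, within a given
brain regional cluster and developmental age window, male donors show lower
between-subject *expression similarity* — the mean of all pairwise Pearson
correlations between donors' transcriptome-wide expression profiles — than
female donors; whether the genes driving such a difference (genes with a
high male/female ratio of expression standard deviation, "variability
genes") replicate in independent data; and whether those genes are
co-expressed with genes at GWAS schizophrenia risk loci in males.

Three design features of the data shape every statistic:

* **Repeated measures.** Most donors contribute samples from many regions.
  Two samples from one donor are nearly perfectly correlated; any naive
  pooled correlation would be dominated by that artifact.
* **Unequal group sizes.** Male and female donor counts differ by stratum;
  similarity estimates rise mechanically with subject count.
* **Small strata.** After stratifying 16 regions into 4 clusters and 13 age
  periods into 11 overlapping 3-period age-bins, a stratum typically holds
  2-8 donors per sex.

# The estimator

For a (regional cluster, age-bin) stratum, similarity is estimated per sex
by a three-stage resampling procedure:

1. **One sample per donor**, selected uniformly, removing within-donor
   non-independence.
2. **Donor bootstrap reduced to the unique set**, per sex, so a donor can
   never be paired with itself.
3. **Equal-n subsampling**: the larger sex's unique set is subsampled
   without replacement to the smaller sex's count.

The per-draw statistic is the mean of the upper-triangular Pearson
correlation matrix between the selected subjects' profiles. The point
estimate is the mean over 100 draws (`n_point_resamples`); the 95%
confidence interval is the empirical 2.5th/97.5th percentile of the draws,
with linear interpolation between order statistics.

The cluster-level sex difference is `D = mean over included bins of
(female - male)` point estimates, so that lower male similarity makes `D`
positive. Significance comes from a donor-level permutation: sex labels are
shuffled *among the donors of each stratum* (every sample of a donor keeps
one label; per-sex donor counts — and therefore the stage-3 subsample sizes
— are preserved) and `D` recomputed; the two-sided empirical p-value is the
fraction of permutations with `|D_perm| >= |D_obs|`, Bonferroni-corrected
over the clusters tested. A p-value of 0 is reported together with its
resolution bound `p_lt = 1/n_null_resamples`, since an empirical p can
never be established below the permutation resolution.

Strata with fewer than `min_donors_per_sex = 2` donors in either sex are
excluded from two-sex analyses, mirroring the treatment of single-donor
strata in the source cohort.

## Variability genes

Within a stratum, the same resampling yields per-draw per-gene standard
deviations across the selected subjects of each sex; these are averaged
over the 100 draws and the genes ranked by the male/female ratio of the
averages. The top 100 (`top_k`, an arbitrary but fixed cut-off) form the
stratum's variability-gene set. Genes whose female SD falls below
`female_sd_floor = 1e-8` are excluded before ranking — the ratio is
undefined at zero female variance and such genes carry no usable signal.
Ties are broken by larger male SD, then lexicographic gene id, making
selection fully deterministic given a seed.

## Co-expression with risk genes

One gene is selected per GWAS risk locus: the gene whose body (1-based
inclusive coordinates; distance 0 inside the gene) lies closest to the
locus's most significant index variant. Genes overlapping the MHC region
(default chr6:25-34 Mb, GRCh37 convention) are never selected because of
its extended linkage disequilibrium; a gene reachable from several loci is
counted once. Distance ties are broken by lexicographic gene id — the
selection rule needs *a* deterministic tie-break and no natural ordering
exists.

Co-expression between a variability-gene set and the risk set is the
median of all between-set pairwise Pearson correlations across male
subjects, averaged over male-only resamples (stages 1-2 only; equal-n
subsampling is meaningless in a one-sex analysis). The null model replaces
the variability set by *variance-matched* random sets: for each real gene,
a random gene with expression SD within 5% (`sd_match_tolerance`) is drawn
without reuse inside one null set, excluding the reference gene itself.
When a gene has no candidate in its window the window is doubled stepwise
(at most 4 times, logged) — a pragmatic fallback for sparse SD
neighbourhoods that leaves the nominal matching intact for every gene that
has neighbours. The one-sided empirical p is the fraction of null sets
whose co-expression is at least as high as observed, corrected for the 22
variability-gene sets tested (11 bins x 2 cortical clusters).

Scoring each of the 1000 null sets with the full 100 inner draws is the
most expensive step of the whole analysis; by default each null set is
scored with `n_null_inner_coexpr = 10` draws. The observed statistic
averages draws to reduce resampling noise; the null distribution needs the
*spread across gene sets*, to which inner-draw noise contributes a small
widening that makes the test slightly conservative. A config switch
restores the full inner count.

## Specificity comparisons and age windows

Four alternative "risk" selections quantify specificity: a random gene per
locus, genes from random same-chromosome windows matched within 10% on
common-variant density (window search by uniform random starts, at most
10,000 attempts per locus; the window search strategy is an
implementation choice), random same-chromosome genes, and external
gene lists read from plain files. The age-window scan slides a window of 4
consecutive distinct donor ages (step 1) across a cluster's pooled bins and
reports the per-window similarity difference restricted to the combined
variability genes, the male-only co-expression, and the mean donor age.

# Preprocessing

The pipeline runs, in order: RIN filtering (donor-level rule for the exon
microarray dialect: remove donors with **more than** 25% of samples below
RIN 7.5; sample-level rule for RNA-seq: remove samples with RIN **<= 7.5**),
log2 transformation (offset 1 for RPKM, 0 for intensities), removal of
donors **strictly older** than 40 years and of non-autosomal genes, the
RNA-seq expression filter (drop genes below 1 RPKM in **more than** 50% of
male or of female samples), quantile normalization, replicate collapsing
(per-gene medians per donor-region pair), mean imputation of missing pH,
surrogate-variable estimation, residualization, and per-sex PCA outlier
removal. Boundary semantics are deliberately asymmetric between the two RIN
dialects; each is kept exactly as stated. The executed order is recorded in
the dataset's transform log and double application of a transform is a
state error.

Covariate adjustment replaces each gene by its least-squares residuals
against an intercept, age, PMI, RIN, pH, batch (when present and variable)
and any surrogate variables. Sex is **never** regressed out: sex effects on
variability are the signal under study. Age enters the model to prevent
artifactual gene-gene correlation through a shared age trend, which matters
most in wide age-bins.

The surrogate-variable count is estimated by a permutation analogue of the
asymptotic approach: residualize against the full model (including sex),
standardize rows, take the singular-value spectrum, and compare it with the
spectrum of row-permuted matrices that are re-residualized and
re-standardized the same way (the permuted null must share the observed
rank reduction, or the comparison is biased). The estimate is the length of
the leading run of observed singular values exceeding the 99th null
percentile at their rank, with 100 permutations. We use 100 permutations
and the 99th percentile rather than a smaller, more liberal null because
with B permutations the rank-1 exceedance probability under exchangeability
is about 1/(B+1); at B = 20 and the 95th percentile the estimator would
report a spurious factor in roughly 5% of pure-noise datasets, which we
judged miscalibrated for a quantity that is usually 0 in this data type.
The count can also be fixed in the configuration, bypassing estimation.

Outliers are flagged separately per sex: samples deviating more than 3 SD
from the mean of either of the first two principal components of that
sex's covariate-adjusted samples (centered, unscaled), in a single pass
with no refitting. The per-axis rule (rather than a joint Mahalanobis
rule) is the minimal reading of "deviates on the first two components";
both agree on clearly displaced samples. Note the finite-sample bound
`(n-1)/sqrt(n)` on a standardized score: with fewer than ~10 samples per
sex no single outlier *can* exceed 3 SD, so the rule is only meaningful at
realistic cohort sizes; a sex with fewer than 4 samples is skipped with a
warning.

# Randomness contract

All stochastic stages derive integer sub-seeds from one master seed and a
string key (a polynomial hash), so every stage is reproducible in
isolation and results do not depend on the order in which strata are
evaluated. Within one estimate the random-number consumption order is part
of the documented contract (one draw per donor, one bootstrap per sex in
the order male-then-female, at most one subsample), which is what allows an
independent re-implementation sharing the seed stream to reproduce every
draw exactly — the basis of the oracle-equivalence tests.

# The synthetic cohort generator

`simulate_study()` generates a full study: donors spread over configurable
age periods with multiple regional samples, technical replicates, RIN/PMI/
pH covariates with missing pH, batch factors, a toy two-chromosome genome
(plus an X block) with non-overlapping genes, risk loci whose closest genes
are the planted risk set, a decoy locus inside an MHC-like exclusion
window, and a uniform common-variant density track.

Expression is simulated on the log2 scale and exponentiated, so the
pipeline's own log2 step is exercised. Per gene and sample:

```
x = mu_g + age trend + covariate terms + batch factors
    + regional signatures + w_g * f_donor + noise
```

* **Regional signatures** act at two levels: a cluster-level signature
  shared by all regions of a regional cluster (the within-cluster
  expression similarity that motivated the cluster definitions) and a
  smaller region-specific part. They are the structure that survives
  covariate residualization — a linear covariate model does not encode
  region — and therefore what makes between-subject correlations positive,
  as in real data where regional identity and nonlinear developmental
  programs play this role. Signature magnitudes scale with each gene's
  noise SD (scales `cluster_effect_sd = 2.3`, `region_effect_sd = 0.3`
  relative to it), reflecting that dynamically regulated genes are both
  noisy and regionally patterned, and keeping the shared-variance fraction
  uniform across the SD spectrum.
* **Male variance inflation**: a designated fraction (default 10%) of
  genes has its noise SD multiplied by `lambda` (default 2) in male
  samples, optionally restricted to designated periods/regions.
* **Latent risk factor**: a standard-normal factor per donor loads on the
  inflated genes and on the planted risk set with loading `c * sigma_g`,
  where `c` solves `c^2 / sqrt((c^2 + lambda^2)(c^2 + 1)) = rho_star`, so
  the expected male cross-correlation between the two sets equals
  `rho_star` (default 0.3) *including* the inflation.
* **Noise SDs**: signal genes draw sigma from (0.8, 1.3) — selected-by-
  variability genes sit among the more variable genes — while background
  genes are a mixture of a moderate component U(0.2, 0.8) and a 25%
  high-variance component U(1.2, 3.0). The upper component covers the
  between-subject SD range reached by inflated genes, so the 5%
  variance-matched null universe is dense everywhere, as it is in a
  14,000-gene transcriptome where 100 selected genes always have
  SD-comparable neighbours.

These generator constants were fixed by a pilot power analysis of the
generator itself (not of any test outcome on real data): they are the
weakest structure under which the documented study conditions — inflation
factor 2 on 10% of genes, 10 donors per sex, cross-correlation 0.3 — make
the planted effects recoverable, while keeping every null calibration
property intact. They are defaults, not dials: the validation suite runs
at exactly these values.

What the generator does **not** emulate: realistic transcriptome-wide
correlation structure beyond one factor and the regional signatures,
platform-specific noise (probe effects, GC content — the pipeline accepts
externally GC-normalized RPKM), genotypes and linkage disequilibrium, and
nonlinear developmental trajectories. Passing tests therefore demonstrate
that the estimators recover what they claim *under the stated generative
model*, not that the biological findings themselves are reproduced.

# Validation harness sizes

The validation suite runs end-to-end at desk scale: null calibration uses
200 simulated cohorts of 150 genes and 6 donors/sex with 20 point-resamples
and 200 permutations; recovery and co-expression power use 25 cohorts of
2000 genes with 10 donors/sex spread over periods 1-5 and test cluster 2,
bins 1-3 — the bins fully covered by that cohort design (edge bins of a
truncated period range are partial-coverage artifacts of the synthetic
window, not of the method). The inner resample count inside permutations is
20 and each co-expression null set is scored with 5 draws. These sizes are
statements of the validation design; all were fixed before the suite was
frozen.

# Known limitations

* The default 13-period table is a stand-in reconstructed from published
  age-bin ranges; analyses of real data should supply the original period
  boundaries.
* The empirical p-values inherit the resolution of the permutation count;
  claims below `1/n_null_resamples` are reported as bounds, not values.
* At toy scales (hundreds of genes), SD-matched null sets necessarily
  overlap the planted variability genes, biasing the co-expression null
  upward; the median statistic suppresses this below ~50% contamination,
  and at study scale the effect is small, but micro-benchmarks on tiny
  universes should not be read as power statements.
* Whether surrogate estimation should precede or follow quantile
  normalization is not fixed by the method's description; the pipeline
  estimates surrogates on the normalized, collapsed data immediately
  before residualization.
* The transfer test pools its observed statistic across the supplied
  strata; a per-stratum variant is available through the strata argument.
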
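#' Simulation parameters for BrainSpan-like cohorts
#'
#' Defaults emulate the structure of the real developmental cohort: donors
#' spread over 13 age periods (two per sex per period, giving roughly six
#' donors per sex in each 3-period age-bin), multiple brain-region samples
#' per donor across the 16 region codes, technical replicates, plausible
#' RIN/PMI/pH covariates with missing pH, batch structure, a 10\% subset of
#' genes with male-specific variance inflation (factor 2), and a latent
#' factor linking the inflated genes to a designated risk-gene set with
#' target male cross-correlation 0.3.
#'
#' Two structural choices mirror real brain transcriptomes. First, genes
#' carry regional-identity signatures at two levels: a cluster-level
#' signature shared by all regions of a regional cluster (the expression
#' similarity that motivated the cluster definitions) and a smaller
#' region-specific part. These signatures are what make between-subject
#' profile correlations positive after covariate residualization (a linear
#' covariate model does not encode region), so sex differences in noise can
#' lower male similarity, as in real data. Second, background noise SDs are
#' a mixture of a moderate component and a heavy tail spanning the full
#' range reached by inflated signal genes, so the 5\% variance-matched null
#' universe is dense everywhere, as in a 14k-gene transcriptome where the
#' 100 selected genes always have SD-comparable neighbours. Signal
#' (variability/risk) genes draw their noise SD from (0.8, 1.3), placing
#' them among the more variable genes, as expected for genes selected by
#' expression variability.
#'
#' @param n_genes Number of genes (desk-scale default 2000; every statistic
#'   is scale-free in gene count).
#' @param periods Period indices covered by the cohort.
#' @param donors_per_period Donors per sex in each covered period (scalar
#'   or one value per period).
#' @param regions Region codes sampled for every donor.
#' @param mu_mean,mu_sd Distribution of baseline log2 gene means.
#' @param sigma_range Noise-SD range for the moderate background component.
#' @param sigma_tail_range,sigma_tail_fraction High-variance background
#'   component: this fraction of background genes draws its noise SD from
#'   the upper range, covering the between-subject SDs reached by inflated
#'   signal genes.
#' @param sigma_range_signal Noise-SD range for variability and risk genes.
#' @param cluster_effect_sd Regional-cluster signature scale, relative to
#'   each gene's noise SD.
#' @param region_effect_sd Region-specific signature scale, relative to
#'   each gene's noise SD.
#' @param variability_fraction Fraction of genes with male variance
#'   inflation.
#' @param lambda Male noise-SD multiplier for inflated genes (>= 1).
#' @param inflation_periods,inflation_regions Restrict inflation to these
#'   periods/regions (`NULL` = everywhere).
#' @param n_risk_genes Size of the planted risk-gene set.
#' @param rho_star Target male cross-correlation between variability and
#'   risk genes in [0, 1).
#' @param age_trend_fraction,age_effect_sd Fraction of genes with a linear
#'   age trend and the SD of their slopes (per SD of age).
#' @param rin_effect_sd,pmi_effect_sd,ph_effect_sd Per-gene covariate
#'   effect SDs (per SD of the covariate).
#' @param n_batches,n_batch_factors,batch_loading_sd Batch structure.
#' @param replicate_prob Probability that a donor-region pair carries a
#'   technical replicate.
#' @param missing_ph_rate Fraction of donors with missing pH.
#' @param n_outliers,outlier_magnitude Injected outlier samples and their
#'   displacement in units of each gene's noise SD.
#' @param frac_x_genes Fraction of genes placed on chromosome X (dropped by
#'   the autosome filter).
#' @param rin_range,pmi_range,ph_mean,ph_sd Covariate sampling ranges.
#' @return An object of class `simulation_params` (validated list).
#' @export
simulation_params <- function(n_genes = 2000L,
                              periods = 1:13,
                              donors_per_period = 2L,
                              regions = REGION_CODES,
                              mu_mean = 7, mu_sd = 2,
                              sigma_range = c(0.2, 0.8),
                              sigma_tail_range = c(1.2, 3.0),
                              sigma_tail_fraction = 0.25,
                              sigma_range_signal = c(0.8, 1.3),
                              cluster_effect_sd = 2.3,
                              region_effect_sd = 0.3,
                              variability_fraction = 0.1,
                              lambda = 2,
                              inflation_periods = NULL,
                              inflation_regions = NULL,
                              n_risk_genes = 50L,
                              rho_star = 0.3,
                              age_trend_fraction = 0.3,
                              age_effect_sd = 0.3,
                              rin_effect_sd = 0.05,
                              pmi_effect_sd = 0.02,
                              ph_effect_sd = 0.05,
                              n_batches = 2L,
                              n_batch_factors = 2L,
                              batch_loading_sd = 0.1,
                              replicate_prob = 0.1,
                              missing_ph_rate = 0.2,
                              n_outliers = 0L,
                              outlier_magnitude = 8,
                              frac_x_genes = 0.05,
                              rin_range = c(7.6, 9.8),
                              pmi_range = c(5, 30),
                              ph_mean = 6.5, ph_sd = 0.25) {
  p <- as.list(environment())
  if (p$lambda < 1) stop("lambda must be >= 1", call. = FALSE)
  if (p$rho_star < 0 || p$rho_star >= 1)
    stop("rho_star must lie in [0, 1)", call. = FALSE)
  for (nm in c("variability_fraction", "age_trend_fraction",
               "replicate_prob", "missing_ph_rate", "frac_x_genes",
               "sigma_tail_fraction"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  p$donors_per_period <- rep_len(as.integer(donors_per_period),
                                 length(p$periods))
  bad <- setdiff(p$regions, REGION_CODES)
  if (length(bad))
    stop("unknown region code: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(p, class = "simulation_params")
}

#' Generate a synthetic cohort
#'
#' Donors are assigned a sex, an age drawn uniformly within their period,
#' and one sample per configured region (plus technical replicates with
#' probability `replicate_prob` per donor-region). RIN and PMI are drawn
#' uniformly from plausible ranges, pH per donor from a normal, with
#' missing-pH injection. The hidden column `ph_true` keeps the pre-missing
#' value used when simulating expression.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @param period_table Period table defining the age windows.
#' @return Sample-record data frame (one row per sample).
#' @export
generate_cohort <- function(params, seed = 1L,
                            period_table = default_period_table()) {
  set.seed(seed)
  validate_period_table(period_table)
  max_age <- normalize_age(40, "years")
  rows <- list()
  donor_n <- 0L
  for (k in seq_along(params$periods)) {
    p <- params$periods[k]
    lo <- period_table$lower_days[p]
    hi <- min(period_table$upper_days[p], max_age)
    for (sx in c("M", "F")) {
      for (d in seq_len(params$donors_per_period[k])) {
        donor_n <- donor_n + 1L
        donor <- sprintf("d%03d", donor_n)
        age <- stats::runif(1, lo, hi)
        ph_true <- stats::rnorm(1, params$ph_mean, params$ph_sd)
        ph <- if (stats::runif(1) < params$missing_ph_rate) NA_real_ else
          ph_true
        pmi <- stats::runif(1, params$pmi_range[1], params$pmi_range[2])
        for (reg in params$regions) {
          n_rep <- 1L + (stats::runif(1) < params$replicate_prob)
          for (rep_i in seq_len(n_rep)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sprintf("%s_%s_%d", donor, reg, rep_i),
              donor_id = donor, sex = sx, age_days = age, region = reg,
              rin = stats::runif(1, params$rin_range[1],
                                 params$rin_range[2]),
              pmi_hours = pmi, ph = ph, ph_true = ph_true,
              batch = sprintf("b%d", sample.int(params$n_batches, 1L)),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a toy genome annotation with planted risk loci
#'
#' Lays out `n_genes` non-overlapping 10-kb genes on chromosomes 1 and 2
#' (plus a chromosome-X block of `frac_x_genes`), reserves an MHC-like
#' exclusion window covering a handful of chromosome-1 genes, plants a
#' risk-gene set on the autosomes outside that window, and emits risk loci
#' whose most significant index variant lies inside the planted gene (so
#' closest-gene selection recovers the set exactly), one decoy locus inside
#' the exclusion window, and a uniform common-variant density track.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @return List with `annotation`, `loci`, `density`, `mhc_region`,
#'   `risk_genes` (the planted ids), `mhc_genes`.
#' @export
generate_annotation <- function(params, seed = 1L) {
  set.seed(seed)
  n <- params$n_genes
  gene_len <- 10000L
  spacing <- 25000L
  n_x <- round(params$frac_x_genes * n)
  n_auto <- n - n_x
  n_chr1 <- ceiling(n_auto / 2)
  chrom <- c(rep("1", n_chr1), rep("2", n_auto - n_chr1), rep("X", n_x))
  pos_in_chrom <- unlist(lapply(unique(chrom), function(ch)
    seq_len(sum(chrom == ch))), use.names = FALSE)
  start <- (pos_in_chrom - 1L) * spacing + 1L
  annotation <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    symbol = sprintf("SYN%04d", seq_len(n)),
    chromosome = chrom, start = start, end = start + gene_len - 1L,
    stringsAsFactors = FALSE)
  # MHC-like exclusion window: 5 genes in the middle of chromosome 1
  mhc_idx <- which(chrom == "1")[seq(floor(n_chr1 / 2),
                                     length.out = 5L)]
  mhc_region <- list(chromosome = "1",
                     start = annotation$start[mhc_idx[1]],
                     end = annotation$end[mhc_idx[length(mhc_idx)]])
  mhc_genes <- annotation$gene_id[mhc_idx]
  eligible <- annotation$gene_id[annotation$chromosome %in% AUTOSOMES &
                                   !(annotation$gene_id %in% mhc_genes)]
  risk_genes <- sort(sample(eligible, params$n_risk_genes))
  loci <- lapply(seq_along(risk_genes), function(i) {
    g <- annotation[match(risk_genes[i], annotation$gene_id), ]
    lstart <- max(1L, g$start - 30000L)
    lend <- g$end + 30000L
    variants <- data.frame(
      position = c(round((g$start + g$end) / 2), lend - 1000L),
      p_value = sort(10^-stats::runif(2, 8, 15)))
    list(locus_id = sprintf("locus%03d", i), chromosome = g$chromosome,
         start = lstart, end = lend, variants = variants)
  })
  decoy <- annotation[mhc_idx[3], ]
  loci[[length(loci) + 1L]] <- list(
    locus_id = sprintf("locus%03d", length(loci) + 1L),
    chromosome = decoy$chromosome,
    start = max(1L, decoy$start - 5000L), end = decoy$end + 5000L,
    variants = data.frame(position = round((decoy$start + decoy$end) / 2),
                          p_value = 1e-10))
  density <- do.call(rbind, lapply(unique(chrom), function(ch) {
    len <- max(annotation$end[annotation$chromosome == ch]) + 30000L
    starts <- seq(1L, len, by = 50000L)
    data.frame(chromosome = ch, start = starts,
               end = pmin(starts + 49999L, len), count = 50,
               stringsAsFactors = FALSE)
  }))
  list(annotation = annotation, loci = loci, density = density,
       mhc_region = mhc_region, risk_genes = risk_genes,
       mhc_genes = mhc_genes)
}

# latent-factor loading scale c with corr = c^2 / sqrt((c^2+lambda^2)(c^2+1))
# equal to rho_star between an inflated male gene and a risk gene
factor_loading_scale <- function(rho_star, lambda) {
  if (rho_star == 0) return(0)
  f <- function(u) u / sqrt((u + lambda^2) * (u + 1)) - rho_star
  sqrt(stats::uniroot(f, c(1e-9, 1e9), tol = 1e-12)$root)
}

#' Generate synthetic expression with known ground truth
#'
#' Per gene g and sample s the log2 signal is
#' `mu_g + age trend + covariate terms + batch factors + w_g * f_d + eps`,
#' where `f_d` is a standard-normal latent factor per donor, `w_g` is
#' nonzero for variability and risk genes (scaled so their expected male
#' cross-correlation is `rho_star`), and the noise SD is
#' `sigma_g * lambda` for inflated genes in male samples within the
#' designated periods/regions, `sigma_g` otherwise. Values are
#' exponentiated to the raw intensity scale so the pipeline's own log2
#' step applies.
#'
#' @param cohort Sample records from [generate_cohort()].
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @param annotation Optional annotation (from [generate_annotation()]);
#'   planted gene sets are then drawn from autosomal non-excluded genes.
#' @param risk_genes Optional pre-planted risk-gene ids.
#' @param exclude_genes Gene ids never planted (e.g. MHC-window genes).
#' @param period_table Period table for inflation designation.
#' @return List with `dataset` (an `expression_dataset` on intensity
#'   scale) and `truth` (planted variability genes, lambda, risk genes,
#'   rho_star, loading scale, batch factor count, outlier sample ids).
#' @export
generate_expression <- function(cohort, params, seed = 1L,
                                annotation = NULL, risk_genes = NULL,
                                exclude_genes = character(),
                                period_table = default_period_table()) {
  set.seed(seed)
  n_g <- params$n_genes
  gene_ids <- if (!is.null(annotation)) annotation$gene_id else
    sprintf("g%04d", seq_len(n_g))
  stopifnot(length(gene_ids) == n_g)
  autosomal <- if (!is.null(annotation))
    gene_ids[annotation$chromosome %in% AUTOSOMES] else gene_ids
  plantable <- setdiff(autosomal, exclude_genes)
  n_var <- round(params$variability_fraction * n_g)
  variability_genes <- sort(sample(setdiff(plantable, risk_genes), n_var))
  if (is.null(risk_genes))
    risk_genes <- sort(sample(setdiff(plantable, variability_genes),
                              params$n_risk_genes))
  signal <- gene_ids %in% c(variability_genes, risk_genes)
  mu <- stats::rnorm(n_g, params$mu_mean, params$mu_sd)
  tail_gene <- stats::runif(n_g) < params$sigma_tail_fraction
  sigma <- ifelse(signal,
                  stats::runif(n_g, params$sigma_range_signal[1],
                               params$sigma_range_signal[2]),
                  ifelse(tail_gene,
                         stats::runif(n_g, params$sigma_tail_range[1],
                                      params$sigma_tail_range[2]),
                         stats::runif(n_g, params$sigma_range[1],
                                      params$sigma_range[2])))
  cc <- factor_loading_scale(params$rho_star, params$lambda)
  w <- ifelse(signal, cc * sigma, 0)
  n_s <- nrow(cohort)
  zscore <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / stats::sd(x)
  trend <- sample(c(TRUE, FALSE), n_g, replace = TRUE,
                  prob = c(params$age_trend_fraction,
                           1 - params$age_trend_fraction))
  beta_age <- ifelse(trend, stats::rnorm(n_g, 0, params$age_effect_sd), 0)
  beta_rin <- stats::rnorm(n_g, 0, params$rin_effect_sd)
  beta_pmi <- stats::rnorm(n_g, 0, params$pmi_effect_sd)
  beta_ph <- stats::rnorm(n_g, 0, params$ph_effect_sd)
  x <- outer(mu, rep(1, n_s)) +
    outer(beta_age, zscore(cohort$age_days)) +
    outer(beta_rin, zscore(cohort$rin)) +
    outer(beta_pmi, zscore(cohort$pmi_hours)) +
    outer(beta_ph, zscore(cohort$ph_true))
  # regional identity: a cluster-level signature shared by all regions of a
  # cluster plus a smaller region-specific part; signature magnitudes scale
  # with each gene's noise SD (dynamically regulated genes are both noisy
  # and regionally patterned), keeping the shared-variance fraction uniform
  # across the SD spectrum
  clusters <- default_region_clusters()
  region_cluster <- vapply(REGION_CODES, function(r)
    clusters$cluster_id[vapply(clusters$member_regions, function(m)
      r %in% m, logical(1))], integer(1))
  clus_sig <- matrix(stats::rnorm(n_g * nrow(clusters), 0,
                                  params$cluster_effect_sd), nrow = n_g)
  reg_sig <- matrix(stats::rnorm(n_g * length(REGION_CODES), 0,
                                 params$region_effect_sd), nrow = n_g)
  reg_idx <- match(cohort$region, REGION_CODES)
  x <- x + (clus_sig[, region_cluster[reg_idx], drop = FALSE] +
              reg_sig[, reg_idx, drop = FALSE]) * sigma
  if (params$n_batch_factors > 0L && params$n_batches > 1L) {
    batches <- sort(unique(cohort$batch))
    z <- matrix(stats::rnorm(length(batches) * params$n_batch_factors),
                nrow = length(batches))
    loadings <- matrix(stats::rnorm(n_g * params$n_batch_factors, 0,
                                    params$batch_loading_sd), nrow = n_g)
    x <- x + loadings %*% t(z[match(cohort$batch, batches), , drop = FALSE])
  }
  donors <- unique(cohort$donor_id)
  f <- stats::rnorm(length(donors))
  x <- x + outer(w, f[match(cohort$donor_id, donors)])
  periods <- assign_periods(cohort$age_days, period_table)
  in_scope <- (cohort$sex == "M") &
    (if (is.null(params$inflation_periods)) TRUE else
      periods %in% params$inflation_periods) &
    (if (is.null(params$inflation_regions)) TRUE else
      cohort$region %in% params$inflation_regions)
  sd_mat <- outer(sigma, rep(1, n_s))
  inflated <- gene_ids %in% variability_genes
  sd_mat[inflated, in_scope] <- sd_mat[inflated, in_scope] * params$lambda
  x <- x + matrix(stats::rnorm(n_g * n_s), n_g, n_s) * sd_mat
  outlier_samples <- character()
  if (params$n_outliers > 0L) {
    out_idx <- sample.int(n_s, min(params$n_outliers, n_s))
    outlier_samples <- cohort$sample_id[out_idx]
    for (s_i in out_idx)
      x[, s_i] <- x[, s_i] + params$outlier_magnitude * sigma
  }
  genes <- if (!is.null(annotation)) annotation else
    data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "donor_id", "sex", "age_days", "region",
                 "rin", "pmi_hours", "ph", "batch")
  ds <- expression_dataset(2^x, genes, cohort[, meta_cols],
                           scale = "intensity")
  truth <- list(variability_genes = variability_genes,
                lambda = params$lambda,
                risk_genes = risk_genes, rho_star = params$rho_star,
                loading_scale = cc,
                n_batch_factors = params$n_batch_factors,
                outlier_samples = outlier_samples)
  list(dataset = ds, truth = truth)
}

#' Simulate a complete study: cohort, genome, expression, loci, density
#'
#' Convenience wrapper chaining [generate_cohort()],
#' [generate_annotation()] and [generate_expression()] under sub-seeds
#' derived from one master seed, so identical parameters and seed give
#' identical output.
#'
#' @param params A [simulation_params()] object.
#' @param seed Master seed.
#' @param period_table Period table.
#' @return List with `dataset`, `truth`, `annotation`, `loci`, `density`,
#'   `mhc_region`.
#' @export
simulate_study <- function(params = simulation_params(), seed = 1L,
                           period_table = default_period_table()) {
  cohort <- generate_cohort(params, derive_seed(seed, "cohort"),
                            period_table)
  gen <- generate_annotation(params, derive_seed(seed, "annotation"))
  expr <- generate_expression(cohort, params,
                              derive_seed(seed, "expression"),
                              annotation = gen$annotation,
                              risk_genes = gen$risk_genes,
                              exclude_genes = gen$mhc_genes,
                              period_table = period_table)
  list(dataset = expr$dataset, truth = expr$truth,
       annotation = gen$annotation, loci = gen$loci, density = gen$density,
       mhc_region = gen$mhc_region)
}
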
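#' Build (regional cluster, age-bin) strata
#'
#' One stratum per cluster and bin, holding all samples whose region lies
#' in the cluster and whose donor age falls in one of the bin's member
#' periods. Bins overlap, so a donor appears in every bin whose window
#' covers its age. Strata with fewer than `cfg$min_donors_per_sex` donors
#' in either sex are emitted but flagged `excluded` for two-sex analyses.
#'
#' @param ds A preprocessed `expression_dataset`.
#' @param period_table Period table (see [default_period_table()]).
#' @param clusters Regional cluster table (see
#'   [default_region_clusters()]).
#' @param cfg An [analysis_config()].
#' @return List of stratum objects: each has `cluster_id`, `bin_index`,
#'   `sample_ids`, `donors` (in first-appearance order), `donor_samples`
#'   (named list), `donor_sex` (named vector), `n_male_donors`,
#'   `n_female_donors`, `excluded`.
#' @export
build_strata <- function(ds, period_table = default_period_table(),
                         clusters = default_region_clusters(),
                         cfg = analysis_config()) {
  bins <- make_age_bins(period_table, cfg$bin_width_periods)
  periods <- assign_periods(ds$samples$age_days, period_table)
  strata <- list()
  for (ci in seq_len(nrow(clusters))) {
    regions <- clusters$member_regions[[ci]]
    in_cluster <- ds$samples$region %in% regions
    for (bi in seq_len(nrow(bins))) {
      in_bin <- periods %in% bins$member_periods[[bi]]
      s <- ds$samples[in_cluster & in_bin, , drop = FALSE]
      donors <- unique(s$donor_id)
      donor_samples <- split(s$sample_id, factor(s$donor_id, levels = donors))
      donor_sex <- vapply(donor_samples, function(ids)
        s$sex[match(ids[1], s$sample_id)], character(1))
      n_m <- sum(donor_sex == "M")
      n_f <- sum(donor_sex == "F")
      strata[[length(strata) + 1L]] <- structure(list(
        cluster_id = clusters$cluster_id[ci],
        bin_index = bins$bin_index[bi],
        sample_ids = s$sample_id,
        donors = donors,
        donor_samples = donor_samples,
        donor_sex = donor_sex,
        n_male_donors = n_m,
        n_female_donors = n_f,
        excluded = n_m < cfg$min_donors_per_sex ||
          n_f < cfg$min_donors_per_sex
      ), class = "stratum")
    }
  }
  strata
}

#' @export
print.stratum <- function(x, ...) {
  cat("<stratum> cluster ", x$cluster_id, ", bin ", x$bin_index, ": ",
      length(x$sample_ids), " samples, ", x$n_male_donors, " M / ",
      x$n_female_donors, " F donors",
      if (x$excluded) " [excluded]" else "", "\n", sep = "")
  invisible(x)
}

#' Mean pairwise between-subject similarity
#'
#' The core statistic: the mean of the n(n-1)/2 distinct pairwise Pearson
#' correlations between subject expression profiles (matrix columns),
#' taken over the upper triangle of the correlation matrix.
#'
#' @param values Genes x subjects matrix (>= 2 of each).
#' @return A number in [-1, 1].
#' @export
mean_pairwise_similarity <- function(values) {
  if (ncol(values) < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (nrow(values) < 2L) stop("need >= 2 genes", call. = FALSE)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance subject profile: ",
         paste(colnames(values)[sds == 0], collapse = ", "), call. = FALSE)
  cm <- stats::cor(values)
  mean(cm[upper.tri(cm)])
}

#' Per-sex similarity estimates from shared resamples
#'
#' Runs `n_resamples` three-stage draws and computes the mean pairwise
#' similarity separately for the male and female selections of each draw.
#' Both sexes are scored on the same draws, mirroring a single resampling
#' pass through the stratum.
#'
#' @param stratum An included stratum.
#' @param ds The `expression_dataset`.
#' @param cfg An [analysis_config()].
#' @param seed Sub-seed for this estimate; `NULL` continues the current
#'   RNG stream (used inside permutations).
#' @param genes Optional gene ids restricting the profile (default: all).
#' @param sex_assignment Optional permuted donor -> sex map.
#' @param n_resamples Number of draws (default `cfg$n_point_resamples`).
#' @return List of two `similarity_result` objects (`male`, `female`), each
#'   with `estimate`, `ci_low`, `ci_high`, `n_donors`,
#'   `resample_estimates`.
#' @export
estimate_similarity_pair <- function(stratum, ds, cfg = analysis_config(),
                                     seed = NULL, genes = NULL,
                                     sex_assignment = NULL,
                                     n_resamples = cfg$n_point_resamples) {
  if (!is.null(seed)) set.seed(seed)
  vals <- stratum_values(ds, stratum, genes)
  ests <- matrix(NA_real_, n_resamples, 2L)
  for (r in seq_len(n_resamples)) {
    d <- draw_resample(stratum, sex_assignment, cfg)
    if (is.null(d)) next
    ests[r, 1L] <- mean_pairwise_similarity(vals[, d$male_samples,
                                                 drop = FALSE])
    ests[r, 2L] <- mean_pairwise_similarity(vals[, d$female_samples,
                                                 drop = FALSE])
  }
  if (all(is.na(ests[, 1L])))
    return(list(male = unavailable_similarity(stratum, "M"),
                female = unavailable_similarity(stratum, "F")))
  mk <- function(col, sex, n_donors) {
    e <- ests[, col]
    ci <- stats::quantile(e, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    structure(list(cluster_id = stratum$cluster_id,
                   bin_index = stratum$bin_index, sex = sex,
                   estimate = mean(e, na.rm = TRUE),
                   ci_low = ci[1], ci_high = ci[2],
                   n_donors = n_donors, resample_estimates = e,
                   unavailable = FALSE),
              class = "similarity_result")
  }
  list(male = mk(1L, "M", stratum$n_male_donors),
       female = mk(2L, "F", stratum$n_female_donors))
}

unavailable_similarity <- function(stratum, sex) {
  structure(list(cluster_id = stratum$cluster_id,
                 bin_index = stratum$bin_index, sex = sex,
                 estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 n_donors = if (sex == "M") stratum$n_male_donors else
                   stratum$n_female_donors,
                 resample_estimates = numeric(), unavailable = TRUE),
            class = "similarity_result")
}

stratum_values <- function(ds, stratum, genes = NULL) {
  vals <- ds$values[, stratum$sample_ids, drop = FALSE]
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(vals))
    if (length(genes) < 2L)
      stop("fewer than 2 of the requested genes are present", call. = FALSE)
    vals <- vals[genes, , drop = FALSE]
  }
  vals
}

#' Expression similarity for one sex in one stratum
#'
#' Point estimate (mean of `cfg$n_point_resamples` resampled similarities)
#' with an empirical 95\% confidence interval (2.5th / 97.5th percentiles
#' of the resample estimates, linear interpolation between order
#' statistics).
#'
#' @inheritParams estimate_similarity_pair
#' @param sex `"M"` or `"F"`.
#' @return A `similarity_result`.
#' @export
estimate_similarity <- function(stratum, ds, sex = c("M", "F"),
                                cfg = analysis_config(), seed = NULL,
                                genes = NULL) {
  sex <- match.arg(sex)
  pair <- estimate_similarity_pair(stratum, ds, cfg, seed = seed,
                                   genes = genes)
  if (sex == "M") pair$male else pair$female
}

#' Donor-level sex-permutation test of similarity differences
#'
#' The observed statistic D is the mean over a cluster's included age-bins
#' of (female - male) similarity point estimates, so lower male similarity
#' gives positive D. Under the null, donor sex labels are shuffled within
#' each stratum (all samples of a donor always carry the same label, and
#' per-sex donor counts are preserved) and D is recomputed with
#' `cfg$n_null_inner` inner resamples; this is repeated
#' `cfg$n_null_resamples` times. The empirical p-value is the fraction of
#' permutations with |D_perm| >= |D_obs| (two-sided via absolute values),
#' Bonferroni-corrected over the number of clusters tested. When no
#' permutation reaches the observed value the p-value is reported as 0
#' with the resolution bound `p_lt = 1/n_null_resamples`.
#'
#' @param cluster_id Regional cluster to test.
#' @param ds The preprocessed `expression_dataset`.
#' @param strata Strata from [build_strata()].
#' @param cfg An [analysis_config()].
#' @param seed Master seed; substreams are derived per stratum and
#'   permutation.
#' @param genes Optional gene restriction (used by transfer analyses).
#' @param m Number of clusters in the Bonferroni family (default 4).
#' @return A `sex_difference_result` with `mean_difference`, `empirical_p`,
#'   `p_lt`, `corrected_p`, `n_permutations`, `included_bins`,
#'   `bin_differences`, `null_differences`.
#' @export
sex_difference_test <- function(cluster_id, ds, strata,
                                cfg = analysis_config(), seed = cfg$seed,
                                genes = NULL, m = 4L) {
  cl_strata <- Filter(function(s) s$cluster_id == cluster_id && !s$excluded,
                      strata)
  if (!length(cl_strata))
    stop("no included strata in cluster ", cluster_id, call. = FALSE)
  obs_diff <- vapply(cl_strata, function(st) {
    pair <- estimate_similarity_pair(
      st, ds, cfg, seed = derive_seed(seed, "obs", cluster_id, st$bin_index),
      genes = genes)
    pair$female$estimate - pair$male$estimate
  }, numeric(1))
  d_obs <- mean(obs_diff, na.rm = TRUE)
  inner <- null_inner_count(cfg)
  d_null <- numeric(cfg$n_null_resamples)
  for (b in seq_len(cfg$n_null_resamples)) {
    set.seed(derive_seed(seed, "perm", cluster_id, b))
    diffs <- vapply(cl_strata, function(st) {
      perm <- sample(unname(st$donor_sex))
      names(perm) <- st$donors
      pair <- estimate_similarity_pair(st, ds, cfg, seed = NULL,
                                       genes = genes,
                                       sex_assignment = perm,
                                       n_resamples = inner)
      pair$female$estimate - pair$male$estimate
    }, numeric(1))
    d_null[b] <- mean(diffs, na.rm = TRUE)
  }
  p <- mean(abs(d_null) >= abs(d_obs))
  structure(list(cluster_id = cluster_id, mean_difference = d_obs,
                 empirical_p = p,
                 p_lt = if (p == 0) 1 / cfg$n_null_resamples else NULL,
                 corrected_p = bonferroni(p, m),
                 n_permutations = cfg$n_null_resamples,
                 included_bins = vapply(cl_strata, `[[`, integer(1),
                                        "bin_index"),
                 bin_differences = obs_diff,
                 null_differences = d_null),
            class = "sex_difference_result")
}

#' Bonferroni correction
#'
#' @param p A p-value in [0, 1].
#' @param m Number of tests (>= 1).
#' @return min(1, p * m).
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, p * m)
}
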
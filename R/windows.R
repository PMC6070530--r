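#' Sliding age-window fine-mapping
#'
#' Pools the samples of a regional cluster across a set of age-bins and
#' slides a window of `cfg$fine_window_n_ages` consecutive distinct donor
#' ages (step one age) along the pooled age axis. Per window it reports
#' (a) the sex difference of expression similarity restricted to the
#' combined variability genes of the pooled bins (flagged unavailable when
#' a sex has fewer than `cfg$min_donors_per_sex` donors) and (b) the
#' male-only median co-expression of those genes with the risk set, plus
#' the mean donor age of the window.
#'
#' @param ds The preprocessed `expression_dataset`.
#' @param cluster_id Regional cluster to scan.
#' @param bins Age-bin indices pooled for the scan (e.g. `8:10`).
#' @param combined_variability_genes Union of the pooled bins'
#'   variability genes.
#' @param risk_set A `risk_gene_set` (or gene id vector).
#' @param cfg An [analysis_config()].
#' @param seed Master seed.
#' @param period_table,clusters Stratification tables.
#' @return Data frame with one row per window: `window_index`,
#'   `mean_age_days`, `n_male_donors`, `n_female_donors`,
#'   `similarity_difference`, `coexpression_rho`.
#' @export
age_window_scan <- function(ds, cluster_id, bins, combined_variability_genes,
                            risk_set, cfg = analysis_config(),
                            seed = cfg$seed,
                            period_table = default_period_table(),
                            clusters = default_region_clusters()) {
  regions <- clusters$member_regions[[match(cluster_id, clusters$cluster_id)]]
  bin_tab <- make_age_bins(period_table, cfg$bin_width_periods)
  member_periods <- unique(unlist(bin_tab$member_periods[bins]))
  periods <- assign_periods(ds$samples$age_days, period_table)
  pool <- ds$samples[ds$samples$region %in% regions &
                       periods %in% member_periods, , drop = FALSE]
  donor_age <- tapply(pool$age_days, pool$donor_id, `[`, 1L)
  ages <- sort(unique(unname(donor_age)))
  w <- cfg$fine_window_n_ages
  if (length(ages) < w)
    stop("only ", length(ages), " distinct donor ages; need >= ", w,
         call. = FALSE)
  risk_genes <- if (inherits(risk_set, "data.frame")) risk_set$gene_id
    else risk_set
  n_win <- length(ages) - w + 1L
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    win_ages <- ages[k:(k + w - 1L)]
    donors <- names(donor_age)[donor_age %in% win_ages]
    s <- pool[pool$donor_id %in% donors, , drop = FALSE]
    st <- window_stratum(s, cluster_id, k, cfg)
    sim_diff <- NA_real_
    if (!st$excluded) {
      pair <- estimate_similarity_pair(
        st, ds, cfg, seed = derive_seed(seed, "window-sim", cluster_id, k),
        genes = combined_variability_genes)
      sim_diff <- pair$female$estimate - pair$male$estimate
    }
    rho <- NA_real_
    if (st$n_male_donors >= 3L) {
      set.seed(derive_seed(seed, "window-coexpr", cluster_id, k))
      rhos <- numeric(cfg$n_point_resamples)
      n_ok <- 0L
      for (r in seq_len(cfg$n_point_resamples)) {
        d <- draw_male_resample(st, cfg)
        if (is.null(d)) next
        rhos[n_ok + 1L] <- median_cross_correlation(
          ds, combined_variability_genes, risk_genes,
          sample_ids = d$male_samples)
        n_ok <- n_ok + 1L
      }
      if (n_ok > 0L) rho <- mean(rhos[seq_len(n_ok)])
    }
    out[[k]] <- data.frame(
      window_index = k,
      mean_age_days = mean(donor_age[donors]),
      n_male_donors = st$n_male_donors,
      n_female_donors = st$n_female_donors,
      similarity_difference = sim_diff,
      coexpression_rho = rho)
  }
  do.call(rbind, out)
}

window_stratum <- function(samples, cluster_id, window_index, cfg) {
  donors <- unique(samples$donor_id)
  donor_samples <- split(samples$sample_id,
                         factor(samples$donor_id, levels = donors))
  donor_sex <- vapply(donor_samples, function(ids)
    samples$sex[match(ids[1], samples$sample_id)], character(1))
  n_m <- sum(donor_sex == "M")
  n_f <- sum(donor_sex == "F")
  structure(list(cluster_id = cluster_id, bin_index = -window_index,
                 sample_ids = samples$sample_id, donors = donors,
                 donor_samples = donor_samples, donor_sex = donor_sex,
                 n_male_donors = n_m, n_female_donors = n_f,
                 excluded = n_m < cfg$min_donors_per_sex ||
                   n_f < cfg$min_donors_per_sex),
            class = "stratum")
}
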
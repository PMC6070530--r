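#' Analysis configuration
#'
#' Collects every fixed constant of the pipeline in one validated object.
#' Defaults follow the study design: 100 point-estimate resamples, 1000
#' null resamples, a 100-gene variability cut-off, a 5\% window for
#' variance-matched null genes, donor-level RIN filtering at 7.5 with a 25\%
#' bad-sample fraction, removal of donors older than 40 years, the
#' less-than-1-RPKM-in-more-than-50\% expression filter, 3-SD outlier flagging
#' on the first two principal components, age-bins joining 3 consecutive
#' periods, 4-age fine-mapping windows, a 10\% common-variant density
#' tolerance with 20 kbp locus extension, and family-wise error correction
#' over the 22 variability-gene sets arising from 11 age-bins in regional
#' clusters 1 (V1C-STC) and 2 (PFC-MSC).
#'
#' @param seed Integer master seed recorded in run manifests.
#' @param n_point_resamples Resampling repetitions behind every point
#'   estimate (similarity, gene SDs, co-expression).
#' @param n_null_resamples Permutations / null gene-set draws behind every
#'   empirical p-value.
#' @param n_null_inner Inner resample count used when re-estimating the
#'   statistic inside each permutation; `NULL` means use
#'   `n_point_resamples`.
#' @param n_null_inner_coexpr Inner draw count used to score each
#'   variance-matched null gene set in the co-expression test (reduced by
#'   default for tractability).
#' @param top_k Number of top-ratio genes forming a variability-gene set.
#' @param sd_match_tolerance Relative SD window for matched null genes.
#' @param rin_min RNA Integrity Number threshold.
#' @param donor_rin_bad_fraction Donors whose fraction of samples with
#'   RIN < `rin_min` exceeds this are removed (strictly greater).
#' @param max_age_years Donors strictly older than this are removed.
#' @param rpkm_min,rpkm_bad_fraction RNA-seq expression filter: drop a gene
#'   when its fraction of sub-`rpkm_min` samples exceeds `rpkm_bad_fraction`
#'   in either sex.
#' @param outlier_z,outlier_n_pcs Per-sex PCA outlier rule: flag samples
#'   deviating more than `outlier_z` SDs from the mean of any of the first
#'   `outlier_n_pcs` principal components.
#' @param bin_width_periods Consecutive age periods joined into one age-bin.
#' @param fine_window_n_ages Distinct donor ages per sliding fine-mapping
#'   window.
#' @param locus_density_tolerance Relative tolerance when matching loci by
#'   common-variant density.
#' @param locus_extension_bp Extension of matched loci before gene lookup.
#' @param mhc_region List with `chromosome`, `start`, `end`; genes
#'   overlapping it are never selected as risk genes. Default is the GRCh37
#'   MHC convention chr6:25,000,000-34,000,000.
#' @param min_donors_per_sex Minimum donors per sex for a stratum to enter
#'   two-sex analyses.
#' @param tested_clusters_for_fwer Regional clusters whose variability-gene
#'   sets enter the co-expression family (default clusters 1 and 2, giving
#'   m = 22 with 11 age-bins).
#' @param surrogate_count Fixed number of surrogate variables; `NULL` means
#'   estimate it from the data.
#' @param sva_n_perm,sva_quantile Row-permutation count and null-spectrum
#'   quantile for the surrogate-count estimator.
#' @param female_sd_floor Genes whose resample-averaged female SD falls below
#'   this are excluded from ratio ranking (guards infinite ratios).
#' @param resample_max_retries Bounded redraw attempts when a bootstrap
#'   leaves a sex with too few unique donors.
#' @param density_max_attempts Bounded window draws per locus in
#'   density-matched gene selection.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(seed = 1L,
                            n_point_resamples = 100L,
                            n_null_resamples = 1000L,
                            n_null_inner = NULL,
                            n_null_inner_coexpr = 10L,
                            top_k = 100L,
                            sd_match_tolerance = 0.05,
                            rin_min = 7.5,
                            donor_rin_bad_fraction = 0.25,
                            max_age_years = 40,
                            rpkm_min = 1,
                            rpkm_bad_fraction = 0.5,
                            outlier_z = 3,
                            outlier_n_pcs = 2L,
                            bin_width_periods = 3L,
                            fine_window_n_ages = 4L,
                            locus_density_tolerance = 0.10,
                            locus_extension_bp = 20000,
                            mhc_region = list(chromosome = "6",
                                              start = 25e6, end = 34e6),
                            min_donors_per_sex = 2L,
                            tested_clusters_for_fwer = c(1L, 2L),
                            surrogate_count = NULL,
                            sva_n_perm = 100L,
                            sva_quantile = 0.99,
                            female_sd_floor = 1e-8,
                            resample_max_retries = 10L,
                            density_max_attempts = 10000L) {
  cfg <- list(
    seed = as.integer(seed),
    n_point_resamples = as.integer(n_point_resamples),
    n_null_resamples = as.integer(n_null_resamples),
    n_null_inner = if (is.null(n_null_inner)) NULL else as.integer(n_null_inner),
    n_null_inner_coexpr = as.integer(n_null_inner_coexpr),
    top_k = as.integer(top_k),
    sd_match_tolerance = sd_match_tolerance,
    rin_min = rin_min,
    donor_rin_bad_fraction = donor_rin_bad_fraction,
    max_age_years = max_age_years,
    rpkm_min = rpkm_min,
    rpkm_bad_fraction = rpkm_bad_fraction,
    outlier_z = outlier_z,
    outlier_n_pcs = as.integer(outlier_n_pcs),
    bin_width_periods = as.integer(bin_width_periods),
    fine_window_n_ages = as.integer(fine_window_n_ages),
    locus_density_tolerance = locus_density_tolerance,
    locus_extension_bp = locus_extension_bp,
    mhc_region = mhc_region,
    min_donors_per_sex = as.integer(min_donors_per_sex),
    tested_clusters_for_fwer = as.integer(tested_clusters_for_fwer),
    surrogate_count = surrogate_count,
    sva_n_perm = as.integer(sva_n_perm),
    sva_quantile = sva_quantile,
    female_sd_floor = female_sd_floor,
    resample_max_retries = as.integer(resample_max_retries),
    density_max_attempts = as.integer(density_max_attempts)
  )
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  counts <- c("n_point_resamples", "n_null_resamples", "n_null_inner_coexpr",
              "top_k", "outlier_n_pcs", "bin_width_periods",
              "fine_window_n_ages", "min_donors_per_sex", "sva_n_perm",
              "resample_max_retries", "density_max_attempts")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1L || is.na(v) || v < 1L)
      stop("config field '", nm, "' must be a positive count", call. = FALSE)
  }
  fracs <- c("sd_match_tolerance", "donor_rin_bad_fraction",
             "rpkm_bad_fraction", "locus_density_tolerance")
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      stop("config field '", nm, "' must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(cfg$n_null_inner) && cfg$n_null_inner < 1L)
    stop("config field 'n_null_inner' must be a positive count", call. = FALSE)
  mhc <- cfg$mhc_region
  if (!all(c("chromosome", "start", "end") %in% names(mhc)))
    stop("mhc_region must have chromosome, start, end", call. = FALSE)
  invisible(cfg)
}

#' Read a flat key/value configuration file
#'
#' The file is YAML with keys mirroring [analysis_config()] argument names;
#' unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML config file.
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(analysis_config, vals)
}

#' Inner resample count used inside permutations
#' @noRd
null_inner_count <- function(cfg) {
  if (is.null(cfg$n_null_inner)) cfg$n_point_resamples else cfg$n_null_inner
}

#' Size of the co-expression test family
#'
#' The family-wise error correction multiplies by the number of
#' variability-gene sets tested: one per age-bin in each tested regional
#' cluster (11 x 2 = 22 under defaults).
#'
#' @param cfg An `analysis_config`.
#' @param n_bins Number of age-bins (11 for the default 13-period table).
#' @return Integer family size m.
#' @export
coexpression_fwer_m <- function(cfg, n_bins = 11L) {
  as.integer(n_bins) * length(cfg$tested_clusters_for_fwer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
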
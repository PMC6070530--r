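#' Resample-averaged per-gene expression SDs for both sexes
#'
#' Runs the three-stage resampling and, per draw, computes each gene's
#' sample standard deviation across the selected subjects of each sex; the
#' returned values are means over `cfg$n_point_resamples` draws. Both sexes
#' are scored on the same draws.
#'
#' @param stratum An included stratum.
#' @param ds The `expression_dataset`.
#' @param cfg An [analysis_config()].
#' @param seed Sub-seed; `NULL` continues the current stream.
#' @param genes Optional gene restriction.
#' @return List with numeric vectors `male` and `female` (named by gene).
#' @export
resampled_gene_sd_pair <- function(stratum, ds, cfg = analysis_config(),
                                   seed = NULL, genes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- stratum_values(ds, stratum, genes)
  acc_m <- acc_f <- numeric(nrow(vals))
  n_ok <- 0L
  for (r in seq_len(cfg$n_point_resamples)) {
    d <- draw_resample(stratum, NULL, cfg)
    if (is.null(d)) next
    acc_m <- acc_m + row_sds(vals[, d$male_samples, drop = FALSE])
    acc_f <- acc_f + row_sds(vals[, d$female_samples, drop = FALSE])
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("all resamples were skipped", call. = FALSE)
  out_m <- acc_m / n_ok
  out_f <- acc_f / n_ok
  names(out_m) <- names(out_f) <- rownames(vals)
  list(male = out_m, female = out_f)
}

#' Resample-averaged per-gene SD for one sex
#'
#' @inheritParams resampled_gene_sd_pair
#' @param sex `"M"` or `"F"`.
#' @return Named numeric vector of per-gene SD estimates.
#' @export
resampled_gene_sd <- function(stratum, ds, sex = c("M", "F"),
                              cfg = analysis_config(), seed = NULL,
                              genes = NULL) {
  sex <- match.arg(sex)
  pair <- resampled_gene_sd_pair(stratum, ds, cfg, seed = seed, genes = genes)
  if (sex == "M") pair$male else pair$female
}

row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(pmax(rowSums((x - m)^2), 0) / (n - 1L))
}

#' Select variability genes by male/female SD ratio
#'
#' Ranks genes by the ratio of resample-averaged male to female expression
#' SD and keeps the `cfg$top_k` highest. Genes whose female SD falls below
#' `cfg$female_sd_floor` are excluded (guarding infinite ratios); ties are
#' broken by larger male SD, then lexicographic gene id.
#'
#' @param male_sd,female_sd Named per-gene SD vectors on the same gene
#'   universe (as from [resampled_gene_sd_pair()]).
#' @param cfg An [analysis_config()].
#' @param cluster_id,bin_index Optional stratum key stored as attributes.
#' @return A `variability_gene_set`: data frame with `gene_id`, `sd_ratio`,
#'   `male_sd`, `female_sd`, ratio-descending.
#' @export
select_variability_genes <- function(male_sd, female_sd,
                                     cfg = analysis_config(),
                                     cluster_id = NULL, bin_index = NULL) {
  if (!identical(names(male_sd), names(female_sd)))
    stop("male and female SD vectors must share one gene universe",
         call. = FALSE)
  eligible <- is.finite(male_sd) & is.finite(female_sd) &
    female_sd >= cfg$female_sd_floor
  ids <- names(male_sd)[eligible]
  ratio <- male_sd[eligible] / female_sd[eligible]
  ord <- order(-ratio, -male_sd[eligible], ids)
  k <- cfg$top_k
  if (length(ids) < k) {
    warning("only ", length(ids), " eligible genes (< top_k = ", k, ")",
            call. = FALSE)
    k <- length(ids)
  }
  sel <- ord[seq_len(k)]
  structure(data.frame(gene_id = ids[sel], sd_ratio = unname(ratio[sel]),
                       male_sd = unname(male_sd[eligible][sel]),
                       female_sd = unname(female_sd[eligible][sel]),
                       stringsAsFactors = FALSE),
            class = c("variability_gene_set", "data.frame"),
            cluster_id = cluster_id, bin_index = bin_index)
}

#' Draw a variance-matched random gene set
#'
#' For each reference gene, one replacement gene is chosen uniformly among
#' genes (other than the reference gene itself, and not yet used within
#' this set) whose SD lies within `tol` of the reference gene's SD in
#' relative terms. When a gene has no eligible match the window is doubled
#' stepwise (at most 4 doublings, logged); if still empty, an error.
#'
#' @param reference Character vector of reference gene ids (or a
#'   `variability_gene_set`).
#' @param sd_table Named per-gene SD vector over the candidate universe
#'   (must cover the reference genes).
#' @param tol Relative SD window (default the configured 5\%).
#' @param seed Optional sub-seed; `NULL` continues the current stream.
#' @return Character vector of replacement gene ids (same length, no
#'   duplicates).
#' @export
matched_random_geneset <- function(reference, sd_table, tol = 0.05,
                                   seed = NULL) {
  if (inherits(reference, "variability_gene_set"))
    reference <- reference$gene_id
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(match(reference, names(sd_table))))
    stop("sd_table does not cover all reference genes", call. = FALSE)
  universe <- names(sd_table)
  out <- character(length(reference))
  used <- character()
  for (i in seq_along(reference)) {
    g <- reference[i]
    target <- sd_table[[g]]
    t_i <- tol
    elig <- character()
    for (step in 0:4) {
      elig <- universe[abs(sd_table - target) <= t_i * target &
                         universe != g & !(universe %in% used)]
      if (length(elig)) break
      t_i <- t_i * 2
      if (step < 4)
        message("widening SD window to ", signif(t_i, 3), " for gene ", g)
    }
    if (!length(elig))
      stop("no SD-matched candidate for gene ", g, call. = FALSE)
    out[i] <- elig[sample.int(length(elig), 1L)]
    used <- c(used, out[i])
  }
  out
}

#' Transfer test of variability genes in a second dataset
#'
#' Tests whether a variability-gene set identified in one dataset also
#' shows decreased male expression similarity in an independent dataset:
#' the observed statistic is the mean over included strata of the
#' (female - male) similarity difference restricted to the gene set; the
#' null scores `cfg$n_null_resamples` variance-matched random gene sets
#' identically (with `cfg$n_null_inner` inner resamples). The one-sided
#' empirical p-value is the fraction of null differences at least as large
#' as the observed one (direction: male decrease).
#'
#' SD matching uses plain per-gene SDs over the male samples pooled across
#' the tested strata of the second dataset.
#'
#' @param ds2 The replication `expression_dataset`.
#' @param geneset Character vector of gene ids (or a
#'   `variability_gene_set`).
#' @param strata2 Strata built on `ds2`.
#' @param cfg An [analysis_config()].
#' @param seed Master seed.
#' @return List with `difference` (observed D), `empirical_p`,
#'   `null_differences`, `n_genes_used`, `fraction_present`.
#' @export
transfer_test <- function(ds2, geneset, strata2, cfg = analysis_config(),
                          seed = cfg$seed) {
  if (inherits(geneset, "variability_gene_set")) geneset <- geneset$gene_id
  present <- intersect(geneset, ds2$genes$gene_id)
  if (length(present) < 20L)
    stop("fewer than 20 variability genes present in the second dataset",
         call. = FALSE)
  frac <- length(present) / length(geneset)
  message(sprintf("%d/%d variability genes present (%.0f%%)",
                  length(present), length(geneset), 100 * frac))
  incl <- Filter(function(s) !s$excluded, strata2)
  if (!length(incl)) stop("no included strata in the second dataset",
                          call. = FALSE)
  score <- function(genes, n_resamples) {
    diffs <- vapply(incl, function(st) {
      pair <- estimate_similarity_pair(st, ds2, cfg, seed = NULL,
                                       genes = genes,
                                       n_resamples = n_resamples)
      pair$female$estimate - pair$male$estimate
    }, numeric(1))
    mean(diffs, na.rm = TRUE)
  }
  set.seed(derive_seed(seed, "transfer-obs"))
  d_obs <- score(present, cfg$n_point_resamples)
  male_samples <- unique(unlist(lapply(incl, function(st)
    unlist(st$donor_samples[st$donor_sex == "M"], use.names = FALSE))))
  sd_table <- row_sds(ds2$values[, male_samples, drop = FALSE])
  names(sd_table) <- ds2$genes$gene_id
  sd_table <- sd_table[sd_table > cfg$female_sd_floor]
  inner <- null_inner_count(cfg)
  d_null <- numeric(cfg$n_null_resamples)
  for (b in seq_len(cfg$n_null_resamples)) {
    set.seed(derive_seed(seed, "transfer-null", b))
    gs <- matched_random_geneset(present, sd_table,
                                 tol = cfg$sd_match_tolerance)
    d_null[b] <- score(gs, inner)
  }
  list(difference = d_obs,
       empirical_p = mean(d_null >= d_obs),
       null_differences = d_null,
       n_genes_used = length(present),
       fraction_present = frac)
}
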
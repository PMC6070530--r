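#' Distance from a position to a gene body
#'
#' Zero when the position lies within [start, end] (1-based inclusive),
#' otherwise the distance to the nearer gene edge.
#' @noRd
gene_distance <- function(position, start, end) {
  ifelse(position >= start & position <= end, 0,
         pmin(abs(position - start), abs(position - end)))
}

overlaps_region <- function(chrom, start, end, region) {
  chrom == region$chromosome & start <= region$end & end >= region$start
}

locus_candidates <- function(locus, annotation) {
  hit <- annotation$chromosome == locus$chromosome &
    annotation$start <= locus$end & annotation$end >= locus$start
  annotation[hit, , drop = FALSE]
}

#' Select one risk gene per GWAS locus by index-variant proximity
#'
#' Per locus: the index variant with the smallest association p-value is
#' taken; among the locus's annotated candidate genes the one minimizing
#' gene-body distance to that variant is selected (distance 0 inside the
#' gene; ties broken by lexicographic gene id). Genes overlapping the MHC
#' region are never selected, genes absent from the annotation are dropped
#' with a message, and a gene reachable from several loci appears exactly
#' once.
#'
#' @param loci List of risk loci (see [read_risk_loci()]).
#' @param annotation Gene annotation table.
#' @param cfg An [analysis_config()] supplying the MHC region.
#' @return A `risk_gene_set`: data frame with `gene_id`, `locus_id`,
#'   `chromosome`, `selection_rule`; attribute `label = "closest"`.
#' @export
select_risk_genes <- function(loci, annotation, cfg = analysis_config()) {
  if (!length(loci)) stop("no risk loci supplied", call. = FALSE)
  rows <- list()
  for (locus in loci) {
    if (nrow(locus$variants) < 1L)
      stop("locus ", locus$locus_id, " has no index variant", call. = FALSE)
    top <- locus$variants[which.min(locus$variants$p_value), ]
    cand <- locus_candidates(locus, annotation)
    cand <- cand[!overlaps_region(cand$chromosome, cand$start, cand$end,
                                  cfg$mhc_region), , drop = FALSE]
    if (nrow(cand) == 0L) {
      message("locus ", locus$locus_id,
              " has no annotated non-MHC candidate gene; skipped")
      next
    }
    d <- gene_distance(top$position, cand$start, cand$end)
    best <- cand[order(d, cand$gene_id)[1L], ]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = best$gene_id, locus_id = locus$locus_id,
      chromosome = best$chromosome, selection_rule = "closest",
      stringsAsFactors = FALSE)
  }
  finish_risk_set(rows, "closest")
}

finish_risk_set <- function(rows, label) {
  if (!length(rows)) stop("no risk genes selected", call. = FALSE)
  tab <- do.call(rbind, rows)
  dup <- duplicated(tab$gene_id)
  if (any(dup))
    message(sum(dup), " duplicate gene(s) across loci collapsed: ",
            paste(unique(tab$gene_id[dup]), collapse = ", "))
  tab <- tab[!dup, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("risk_gene_set", "data.frame"), label = label)
}

#' Random risk gene per locus (specificity procedure I)
#'
#' Like [select_risk_genes()] but ignoring proximity: one candidate gene is
#' chosen uniformly per locus among its annotated non-MHC genes.
#'
#' @inheritParams select_risk_genes
#' @param seed Optional sub-seed; `NULL` continues the current stream.
#' @return A `risk_gene_set` with label `"random_in_locus"`.
#' @export
random_gene_per_locus <- function(loci, annotation, cfg = analysis_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (locus in loci) {
    cand <- locus_candidates(locus, annotation)
    cand <- cand[!overlaps_region(cand$chromosome, cand$start, cand$end,
                                  cfg$mhc_region), , drop = FALSE]
    if (nrow(cand) == 0L) {
      message("locus ", locus$locus_id,
              " has no annotated non-MHC candidate gene; skipped")
      next
    }
    pick <- cand[sample.int(nrow(cand), 1L), ]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = pick$gene_id, locus_id = locus$locus_id,
      chromosome = pick$chromosome, selection_rule = "random_in_locus",
      stringsAsFactors = FALSE)
  }
  finish_risk_set(rows, "random_in_locus")
}

#' Common-variant density of a genomic interval
#'
#' Sums the per-window variant counts of a density track over an interval,
#' weighting partially overlapping windows by their overlap fraction.
#'
#' @param density Data frame with `chromosome`, `start`, `end`, `count`.
#' @param chrom,start,end Interval (1-based inclusive).
#' @return Interpolated variant count.
#' @export
interval_density <- function(density, chrom, start, end) {
  w <- density[density$chromosome == chrom, , drop = FALSE]
  if (!nrow(w)) stop("no density windows on chromosome ", chrom,
                     call. = FALSE)
  ov_start <- pmax(w$start, start)
  ov_end <- pmin(w$end, end)
  frac <- pmax(ov_end - ov_start + 1, 0) / (w$end - w$start + 1)
  sum(w$count * frac)
}

#' Density-matched random loci gene set (specificity procedure II)
#'
#' For each risk locus, windows of the same size are drawn uniformly on the
#' same chromosome until one has a common-variant density within
#' `cfg$locus_density_tolerance` of the original locus (at most
#' `cfg$density_max_attempts` draws, then the locus is skipped with a
#' message); one gene overlapping the matched window extended by
#' `cfg$locus_extension_bp` on each side is then selected uniformly.
#' Windows without overlapping genes count as failed draws.
#'
#' @inheritParams select_risk_genes
#' @param density Per-window common-variant density table.
#' @param seed Optional sub-seed.
#' @return A `risk_gene_set` with label `"density_matched"`.
#' @export
density_matched_loci_geneset <- function(loci, density, annotation,
                                         cfg = analysis_config(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (locus in loci) {
    width <- locus$end - locus$start
    chrom_windows <- density[density$chromosome == locus$chromosome, ,
                             drop = FALSE]
    if (!nrow(chrom_windows)) {
      message("no density track for chromosome ", locus$chromosome,
              "; locus ", locus$locus_id, " skipped")
      next
    }
    chrom_len <- max(chrom_windows$end)
    d0 <- interval_density(density, locus$chromosome, locus$start, locus$end)
    found <- NULL
    for (attempt in seq_len(cfg$density_max_attempts)) {
      s <- sample.int(max(chrom_len - width, 1L), 1L)
      e <- s + width
      d <- interval_density(density, locus$chromosome, s, e)
      if (abs(d - d0) > cfg$locus_density_tolerance * d0) next
      ext <- cfg$locus_extension_bp
      cand <- annotation[annotation$chromosome == locus$chromosome &
                           annotation$start <= e + ext &
                           annotation$end >= s - ext, , drop = FALSE]
      cand <- cand[!overlaps_region(cand$chromosome, cand$start, cand$end,
                                    cfg$mhc_region), , drop = FALSE]
      if (nrow(cand) == 0L) next
      found <- cand[sample.int(nrow(cand), 1L), ]
      break
    }
    if (is.null(found)) {
      message("no density-matched window with genes for locus ",
              locus$locus_id, "; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = found$gene_id, locus_id = locus$locus_id,
      chromosome = found$chromosome, selection_rule = "density_matched",
      stringsAsFactors = FALSE)
  }
  finish_risk_set(rows, "density_matched")
}

#' Same-chromosome random gene set (specificity procedure III)
#'
#' For each reference risk gene, one distinct gene is chosen uniformly from
#' the same chromosome, irrespective of sequence variability, excluding the
#' reference gene, the MHC region, and genes already drawn into the set.
#'
#' @param reference A `risk_gene_set` (or data frame with `gene_id`).
#' @param annotation Gene annotation table.
#' @param cfg An [analysis_config()].
#' @param seed Optional sub-seed.
#' @return A `risk_gene_set` with label `"same_chromosome"`.
#' @export
same_chromosome_geneset <- function(reference, annotation,
                                    cfg = analysis_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  used <- character()
  for (i in seq_len(nrow(reference))) {
    g <- reference$gene_id[i]
    chrom <- annotation$chromosome[match(g, annotation$gene_id)]
    if (is.na(chrom)) {
      message("reference gene ", g, " not annotated; skipped")
      next
    }
    cand <- annotation[annotation$chromosome == chrom &
                         annotation$gene_id != g &
                         !(annotation$gene_id %in% used), , drop = FALSE]
    cand <- cand[!overlaps_region(cand$chromosome, cand$start, cand$end,
                                  cfg$mhc_region), , drop = FALSE]
    if (nrow(cand) == 0L)
      stop("chromosome ", chrom, " has no other selectable gene",
           call. = FALSE)
    pick <- cand[sample.int(nrow(cand), 1L), ]
    used <- c(used, pick$gene_id)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = pick$gene_id, locus_id = NA_character_,
      chromosome = pick$chromosome, selection_rule = "same_chromosome",
      stringsAsFactors = FALSE)
  }
  finish_risk_set(rows, "same_chromosome")
}

#' External comparison gene set (specificity procedures IV-V)
#'
#' Reads a plain gene list (one id per line), keeps annotated autosomal
#' genes, drops unknown ids with a message, and deduplicates.
#'
#' @param path Gene list file.
#' @param annotation Gene annotation table.
#' @param label Set label; defaults to the file basename.
#' @return A `risk_gene_set`.
#' @export
external_geneset <- function(path, annotation, label = NULL) {
  ids <- read_gene_list(path)
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  m <- match(ids, annotation$gene_id)
  if (anyNA(m))
    message(sum(is.na(m)), " unknown gene id(s) dropped: ",
            paste(ids[is.na(m)], collapse = ", "))
  keep <- !is.na(m) & annotation$chromosome[m] %in% AUTOSOMES
  if (!any(keep))
    stop("no annotated autosomal genes in ", path, call. = FALSE)
  rows <- lapply(which(keep), function(i) data.frame(
    gene_id = ids[i], locus_id = NA_character_,
    chromosome = annotation$chromosome[m[i]], selection_rule = "external",
    stringsAsFactors = FALSE))
  finish_risk_set(rows, label)
}

#' Median cross-correlation between two gene sets
#'
#' All pairwise Pearson correlations between the expression vectors of
#' genes in set A and genes in set B across the given samples are computed;
#' the statistic is the median of this |A| x |B| matrix. Pairs where the
#' same gene appears on both sides are excluded; zero-variance genes are
#' dropped with a warning.
#'
#' @param ds An `expression_dataset` (typically male samples only).
#' @param set_a,set_b Gene id vectors (intersected with the dataset).
#' @param sample_ids Optional sample restriction (>= 3 subjects).
#' @return The median cross-set correlation.
#' @export
median_cross_correlation <- function(ds, set_a, set_b, sample_ids = NULL) {
  vals <- ds$values
  if (!is.null(sample_ids)) vals <- vals[, sample_ids, drop = FALSE]
  if (ncol(vals) < 3L) stop("need >= 3 subjects", call. = FALSE)
  a <- intersect(set_a, rownames(vals))
  b <- intersect(set_b, rownames(vals))
  if (!length(a) || !length(b))
    stop("empty gene-set intersection with the dataset", call. = FALSE)
  keep_var <- function(g) {
    sds <- row_sds(vals[g, , drop = FALSE])
    if (any(sds == 0)) {
      warning("zero-variance gene(s) dropped: ",
              paste(g[sds == 0], collapse = ", "), call. = FALSE)
      g <- g[sds > 0]
    }
    g
  }
  a <- keep_var(a)
  b <- keep_var(b)
  if (!length(a) || !length(b))
    stop("no genes with variance left in a set", call. = FALSE)
  cm <- stats::cor(t(vals[a, , drop = FALSE]), t(vals[b, , drop = FALSE]))
  same <- outer(a, b, "==")
  if (all(same)) stop("no valid pairs after self-exclusion", call. = FALSE)
  stats::median(cm[!same])
}

#' Co-expression of variability genes with a risk-gene set
#'
#' The observed statistic is the mean over `cfg$n_point_resamples`
#' male-only resamples (stages 1-2; no equal-n subsampling since only males
#' are scored) of the median cross-correlation between the variability-gene
#' set and the risk set. The null replaces the variability set with
#' `cfg$n_null_resamples` variance-matched random sets (SD within
#' `cfg$sd_match_tolerance` of each real gene, matched on the supplied male
#' SD table), each scored with `cfg$n_null_inner_coexpr` inner draws. The
#' one-sided empirical p-value is the fraction of null co-expression values
#' at least as high as the observed one; the corrected p applies Bonferroni
#' over the `m` variability-gene sets tested (22 under defaults).
#'
#' @param stratum A stratum with >= 3 male donors.
#' @param ds The preprocessed `expression_dataset`.
#' @param variability_set A `variability_gene_set` (or gene id vector).
#' @param risk_set A `risk_gene_set` (or gene id vector).
#' @param sd_table Named male SD table over the gene universe (e.g.
#'   `resampled_gene_sd(stratum, ds, "M", ...)`).
#' @param cfg An [analysis_config()].
#' @param seed Master seed.
#' @param m Bonferroni family size (default [coexpression_fwer_m()]).
#' @return A `coexpression_result`.
#' @export
coexpression_test <- function(stratum, ds, variability_set, risk_set,
                              sd_table, cfg = analysis_config(),
                              seed = cfg$seed, m = coexpression_fwer_m(cfg)) {
  var_genes <- if (inherits(variability_set, "variability_gene_set"))
    variability_set$gene_id else variability_set
  risk_genes <- if (inherits(risk_set, "data.frame")) risk_set$gene_id
    else risk_set
  risk_label <- attr(risk_set, "label") %||% "risk"
  score <- function(genes, n_draws) {
    rhos <- numeric(n_draws)
    n_ok <- 0L
    for (r in seq_len(n_draws)) {
      d <- draw_male_resample(stratum, cfg)
      if (is.null(d)) next
      rhos[n_ok + 1L] <- median_cross_correlation(
        ds, genes, risk_genes, sample_ids = d$male_samples)
      n_ok <- n_ok + 1L
    }
    if (n_ok == 0L) stop("all male resamples skipped", call. = FALSE)
    mean(rhos[seq_len(n_ok)])
  }
  set.seed(derive_seed(seed, "coexpr-obs", stratum$cluster_id,
                       stratum$bin_index))
  rho_obs <- score(var_genes, cfg$n_point_resamples)
  sd_table <- sd_table[is.finite(sd_table) & sd_table > 0]
  null_rho <- numeric(cfg$n_null_resamples)
  for (b in seq_len(cfg$n_null_resamples)) {
    set.seed(derive_seed(seed, "coexpr-null", stratum$cluster_id,
                         stratum$bin_index, b))
    gs <- matched_random_geneset(intersect(var_genes, names(sd_table)),
                                 sd_table, tol = cfg$sd_match_tolerance)
    null_rho[b] <- score(gs, cfg$n_null_inner_coexpr)
  }
  p <- mean(null_rho >= rho_obs)
  structure(list(cluster_id = stratum$cluster_id,
                 bin_index = stratum$bin_index,
                 risk_set_label = risk_label,
                 rho = rho_obs,
                 null_mean = mean(null_rho), null_sd = stats::sd(null_rho),
                 null_quantiles = stats::quantile(null_rho,
                                                  c(0.025, 0.5, 0.975)),
                 empirical_p = p,
                 p_lt = if (p == 0) 1 / cfg$n_null_resamples else NULL,
                 corrected_p = bonferroni(p, m),
                 n_variability_genes = length(var_genes),
                 n_risk_genes = length(risk_genes),
                 null_rhos = null_rho),
            class = "coexpression_result")
}
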
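#' RNA-quality filtering
#'
#' Two dialects are supported. `donor_fraction` (exon microarray) removes
#' every sample of a donor whose fraction of samples with RIN below
#' `cfg$rin_min` strictly exceeds `cfg$donor_rin_bad_fraction` (a donor with
#' exactly 25\% low-RIN samples is kept). `sample_threshold` (RNA-seq /
#' single-region arrays) removes individual samples with RIN less than or
#' equal to `cfg$rin_min`.
#'
#' @param ds An `expression_dataset` with RIN on every sample.
#' @param mode `"donor_fraction"` or `"sample_threshold"`.
#' @param cfg An [analysis_config()].
#' @return The filtered dataset; the applied rule is appended to the
#'   transform log (idempotent: re-filtering removes nothing further).
#' @export
filter_rin <- function(ds, mode = c("donor_fraction", "sample_threshold"),
                       cfg = analysis_config()) {
  mode <- match.arg(mode)
  s <- ds$samples
  if (mode == "donor_fraction") {
    bad_frac <- tapply(s$rin < cfg$rin_min, s$donor_id, mean)
    bad_donors <- names(bad_frac)[bad_frac > cfg$donor_rin_bad_fraction]
    keep <- !(s$donor_id %in% bad_donors)
  } else {
    keep <- s$rin > cfg$rin_min
  }
  out <- subset_samples(ds, s$sample_id[keep])
  label <- paste0("filter_rin:", mode)
  if (!label %in% out$transform_log)
    out$transform_log <- c(out$transform_log, label)
  out
}

#' Remove old donors and non-autosomal genes
#'
#' Samples from donors strictly older than `cfg$max_age_years` are removed
#' (a donor aged exactly 40 years is kept). Genes are restricted to
#' chromosomes 1-22; genes without annotation are dropped with a message.
#'
#' @param ds An `expression_dataset`.
#' @param annotation Optional annotation table to attach first; if `NULL`
#'   the dataset's own gene table must carry `chromosome`.
#' @param cfg An [analysis_config()].
#' @return The filtered dataset.
#' @export
filter_age_and_autosomes <- function(ds, annotation = NULL,
                                     cfg = analysis_config()) {
  if (!is.null(annotation)) ds <- attach_annotation(ds, annotation)
  if (is.null(ds$genes$chromosome))
    stop("gene annotation with chromosomes is required", call. = FALSE)
  cutoff <- normalize_age(cfg$max_age_years, "years")
  ds <- subset_samples(ds, ds$samples$sample_id[ds$samples$age_days <= cutoff])
  unann <- is.na(ds$genes$chromosome)
  if (any(unann))
    message(sum(unann), " genes without annotation dropped")
  keep <- !unann & ds$genes$chromosome %in% AUTOSOMES
  ds <- subset_genes(ds, ds$genes$gene_id[keep])
  if (!"filter_age_and_autosomes" %in% ds$transform_log)
    ds$transform_log <- c(ds$transform_log, "filter_age_and_autosomes")
  ds
}

#' Expression filter for RNA-seq data
#'
#' Drops a gene when the fraction of male samples with expression below
#' `cfg$rpkm_min` strictly exceeds `cfg$rpkm_bad_fraction`, or the same
#' holds among female samples. A gene low in exactly half of each sex is
#' kept. Must run on the raw RPKM scale, before log transformation.
#'
#' @param ds An `expression_dataset` on RPKM scale.
#' @param cfg An [analysis_config()].
#' @return The filtered dataset.
#' @export
filter_rpkm <- function(ds, cfg = analysis_config()) {
  if ("log2_transform" %in% ds$transform_log)
    stop("filter_rpkm requires pre-log RPKM values", call. = FALSE)
  male <- ds$samples$sex == "M"
  low <- ds$values < cfg$rpkm_min
  frac_m <- rowMeans(low[, male, drop = FALSE])
  frac_f <- rowMeans(low[, !male, drop = FALSE])
  keep <- !(frac_m > cfg$rpkm_bad_fraction | frac_f > cfg$rpkm_bad_fraction)
  ds <- subset_genes(ds, ds$genes$gene_id[keep])
  if (!"filter_rpkm" %in% ds$transform_log)
    ds$transform_log <- c(ds$transform_log, "filter_rpkm")
  ds
}

#' Log2-transform expression values
#'
#' @param ds An `expression_dataset` with non-negative values.
#' @param offset Added before taking log2: 1 for RPKM data (so zeros map to
#'   zero), 0 for strictly positive intensity data.
#' @return The transformed dataset; double application is a state error.
#' @export
log2_transform <- function(ds, offset = 1) {
  ds <- log_transform(ds, "log2_transform")
  if (any(ds$values + offset <= 0))
    stop("log2 of non-positive value; check the offset", call. = FALSE)
  ds$values <- log2(ds$values + offset)
  ds$scale <- "log2"
  ds
}

#' Quantile-normalize samples
#'
#' Forces every sample column onto the identical sorted value multiset
#' (the mean of the per-rank order statistics across samples); ties within
#' a column receive the mean of the reference values over their tied rank
#' span. Delegated to [limma::normalizeQuantiles()] with `ties = TRUE`,
#' which implements exactly this dialect.
#'
#' @param ds An `expression_dataset` with at least two samples.
#' @return The normalized dataset.
#' @export
quantile_normalize <- function(ds) {
  if (ncol(ds$values) < 2L)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  ds <- log_transform(ds, "quantile_normalize")
  norm <- limma::normalizeQuantiles(ds$values, ties = TRUE)
  dimnames(norm) <- dimnames(ds$values)
  ds$values <- norm
  ds
}

#' Collapse technical replicates
#'
#' Samples sharing (donor, region) are replaced by a single sample carrying
#' per-gene median values; metadata comes from the first replicate and RIN
#' is the median replicate RIN.
#'
#' @param ds An `expression_dataset`.
#' @return The collapsed dataset (at most one sample per donor-region).
#' @export
collapse_replicates <- function(ds) {
  key <- paste(ds$samples$donor_id, ds$samples$region, sep = "\r")
  if (!anyDuplicated(key)) {
    if (!"collapse_replicates" %in% ds$transform_log)
      ds$transform_log <- c(ds$transform_log, "collapse_replicates")
    return(ds)
  }
  first <- !duplicated(key)
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  values <- vapply(groups, function(ix) {
    if (length(ix) == 1L) ds$values[, ix]
    else apply(ds$values[, ix, drop = FALSE], 1, stats::median)
  }, numeric(nrow(ds$values)))
  samples <- ds$samples[first, , drop = FALSE]
  samples$rin <- vapply(groups, function(ix) stats::median(ds$samples$rin[ix]),
                        numeric(1))
  rownames(samples) <- NULL
  colnames(values) <- samples$sample_id
  ds$values <- values
  ds$samples <- samples
  if (!"collapse_replicates" %in% ds$transform_log)
    ds$transform_log <- c(ds$transform_log, "collapse_replicates")
  ds
}

#' Impute missing brain pH
#'
#' Missing pH values are replaced by the mean of the observed pH across all
#' retained samples.
#'
#' @param ds An `expression_dataset`.
#' @return The dataset with complete pH.
#' @export
impute_ph <- function(ds) {
  ph <- ds$samples$ph
  if (is.null(ph) || all(is.na(ph)))
    stop("all pH values missing; drop pH from the covariate model instead",
         call. = FALSE)
  ph[is.na(ph)] <- mean(ph, na.rm = TRUE)
  ds$samples$ph <- ph
  if (!"impute_ph" %in% ds$transform_log)
    ds$transform_log <- c(ds$transform_log, "impute_ph")
  ds
}

#' Build the covariate model for adjustment
#'
#' The full model contains sex plus all nuisance covariates; the null model
#' is the full model minus sex. Sex effects on expression variability are
#' the signal of interest and are never regressed out: residualization uses
#' the null model only, while the full model serves surrogate-variable
#' estimation.
#'
#' @param samples Sample metadata (complete covariates; run [impute_ph()]
#'   first).
#' @param terms Nuisance covariate names among `age_days`, `pmi_hours`,
#'   `rin`, `ph`, `batch`; terms with any missing value or no variation are
#'   dropped with a message.
#' @param surrogates Optional matrix of surrogate variables
#'   (samples x k), appended to both models.
#' @return List with `full_terms`, `null_terms`, and design matrices
#'   `full_design`, `null_design` (each with intercept).
#' @export
covariate_model <- function(samples,
                            terms = c("age_days", "pmi_hours", "rin", "ph",
                                      "batch"),
                            surrogates = NULL) {
  n <- nrow(samples)
  cols <- list()
  used <- character()
  for (tm in terms) {
    v <- samples[[tm]]
    if (is.null(v) || anyNA(v)) {
      message("covariate '", tm, "' missing or incomplete; dropped from model")
      next
    }
    if (tm == "batch") {
      if (length(unique(v)) < 2L) next
      mm <- stats::model.matrix(~factor(v))[, -1, drop = FALSE]
      colnames(mm) <- paste0("batch", seq_len(ncol(mm)))
      cols[[tm]] <- mm
    } else {
      if (stats::sd(v) == 0) {
        message("covariate '", tm, "' is constant; dropped from model")
        next
      }
      cols[[tm]] <- matrix(v, ncol = 1, dimnames = list(NULL, tm))
    }
    used <- c(used, tm)
  }
  if (!is.null(surrogates)) {
    surrogates <- as.matrix(surrogates)
    if (ncol(surrogates) > 0L) {
      colnames(surrogates) <- paste0("sv", seq_len(ncol(surrogates)))
      cols[["surrogates"]] <- surrogates
      used <- c(used, colnames(surrogates))
    }
  }
  null_design <- cbind(`(Intercept)` = rep(1, n),
                       do.call(cbind, unname(cols)))
  sex_col <- matrix(as.numeric(samples$sex == "M"), ncol = 1,
                    dimnames = list(NULL, "sexM"))
  full_design <- cbind(null_design, sex_col)
  list(full_terms = c(used, "sex"), null_terms = used,
       full_design = full_design, null_design = null_design)
}

#' Estimate the number of surrogate variables
#'
#' Latent-factor count in the residuals of the full covariate model, by an
#' asymptotic permutation analogue: (1) residualize expression against the
#' full model (including sex), (2) standardize residual rows and take the
#' singular-value spectrum, (3) build a null spectrum from `cfg$sva_n_perm`
#' independent within-row permutations, re-residualizing each permuted
#' matrix against the same model so the null shares the observed rank
#' reduction, (4) count the leading observed singular values exceeding the
#' `cfg$sva_quantile` null quantile at the same rank, stopping at the first
#' non-exceedance. Documented as an analogue of the standard asymptotic
#' approach, not a clone; the count can be fixed via `cfg$surrogate_count`
#' to bypass estimation.
#'
#' @param values Gene x sample matrix.
#' @param model A [covariate_model()].
#' @param cfg An [analysis_config()].
#' @param seed Seed for the permutation null.
#' @return Integer estimated surrogate count.
#' @export
estimate_surrogate_count <- function(values, model, cfg = analysis_config(),
                                     seed = 1L) {
  design <- model$full_design
  if (nrow(design) <= ncol(design))
    stop("more model terms than samples", call. = FALSE)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop("degenerate design matrix (collinear terms: ",
         paste(colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]],
               collapse = ", "), ")", call. = FALSE)
  standardize_rows <- function(m) {
    rsd <- apply(m, 1, stats::sd)
    keep <- rsd > 0
    (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) / rsd[keep]
  }
  s <- standardize_rows(t(qr.resid(qr_d, t(values))))
  d_obs <- svd(s, nu = 0, nv = 0)$d
  set.seed(seed)
  d_null <- matrix(NA_real_, cfg$sva_n_perm, length(d_obs))
  for (b in seq_len(cfg$sva_n_perm)) {
    sp <- t(apply(s, 1, sample))
    spr <- standardize_rows(t(qr.resid(qr_d, t(sp))))
    d_null[b, ] <- svd(spr, nu = 0, nv = 0)$d
  }
  thresh <- apply(d_null, 2, stats::quantile, probs = cfg$sva_quantile)
  k <- 0L
  for (i in seq_along(d_obs)) {
    if (d_obs[i] > thresh[i]) k <- k + 1L else break
  }
  k
}

#' Compute surrogate variable values
#'
#' Right singular vectors of the full-model residual matrix for the chosen
#' count; the standard surrogate-variable skeleton.
#'
#' @param values Gene x sample matrix.
#' @param model A [covariate_model()].
#' @param k Number of surrogate variables.
#' @return A samples x k matrix (0 columns when `k = 0`).
#' @export
surrogate_values <- function(values, model, k) {
  if (k == 0L) return(matrix(numeric(0), nrow = ncol(values), ncol = 0))
  res <- t(qr.resid(qr(model$full_design), t(values)))
  sv <- svd(res, nu = 0, nv = k)
  sv$v
}

#' Residualize expression against nuisance covariates
#'
#' Per gene, values are replaced by least-squares residuals against an
#' intercept plus the null-model terms (age, PMI, RIN, pH, batch and
#' surrogate variables when present). Sex is never part of this model, so
#' sex differences in mean and variance survive adjustment.
#'
#' @param ds An `expression_dataset`.
#' @param model A [covariate_model()] built from `ds$samples`.
#' @return The residualized dataset (scale `"residual"`).
#' @export
residualize <- function(ds, model) {
  design <- model$null_design
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop("rank-deficient design; collinear terms: ",
         paste(colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]],
               collapse = ", "), call. = FALSE)
  ds <- log_transform(ds, "residualize")
  ds$values <- t(qr.resid(qr_d, t(ds$values)))
  dimnames(ds$values) <- list(ds$genes$gene_id, ds$samples$sample_id)
  ds$scale <- "residual"
  ds
}

#' Flag and remove expression outliers by per-sex PCA
#'
#' Separately for males and females: samples are scored on the first
#' `cfg$outlier_n_pcs` principal components of that sex's covariate-adjusted
#' samples (centered, unscaled) and flagged when deviating more than
#' `cfg$outlier_z` standard deviations from the component mean on any
#' component. Flagging is one-shot: components are not re-fitted after
#' removal. A sex with fewer than 4 samples is skipped with a warning.
#'
#' @param ds A residualized `expression_dataset`.
#' @param cfg An [analysis_config()].
#' @return List with `flagged` (sample ids) and `dataset` (without them).
#' @export
detect_outliers <- function(ds, cfg = analysis_config()) {
  flagged <- character()
  for (sx in c("M", "F")) {
    ids <- ds$samples$sample_id[ds$samples$sex == sx]
    if (length(ids) < 4L) {
      warning("fewer than 4 ", sx, " samples; outlier detection skipped",
              call. = FALSE)
      next
    }
    x <- t(ds$values[, ids, drop = FALSE])
    npc <- min(cfg$outlier_n_pcs, nrow(x) - 1L, ncol(x))
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = npc)
    for (j in seq_len(npc)) {
      sc <- pr$x[, j]
      dev <- abs(sc - mean(sc))
      flagged <- c(flagged, ids[dev > cfg$outlier_z * stats::sd(sc)])
    }
  }
  flagged <- unique(flagged)
  out <- subset_samples(ds, setdiff(ds$samples$sample_id, flagged))
  if (!"detect_outliers" %in% out$transform_log)
    out$transform_log <- c(out$transform_log, "detect_outliers")
  list(flagged = flagged, dataset = out)
}

#' Run the full preprocessing pipeline
#'
#' Executes, in order: RIN filtering (donor-fraction rule for microarray,
#' sample threshold for RNA-seq), the RNA-seq expression filter, log2
#' transformation, age/autosome filtering, quantile normalization, replicate
#' collapsing, pH imputation, surrogate-variable estimation, covariate
#' residualization, and per-sex PCA outlier removal. The executed order is
#' recorded in the transform log.
#'
#' @param ds Raw `expression_dataset` with metadata and annotation attached.
#' @param cfg An [analysis_config()].
#' @param platform `"microarray"` (intensity scale, donor-fraction RIN rule,
#'   log2 offset 0) or `"rnaseq"` (RPKM scale, sample RIN threshold,
#'   expression filter, log2 offset 1).
#' @param seed Seed for surrogate-count estimation.
#' @param covariate_terms Nuisance covariates for [covariate_model()].
#' @return List with `dataset` (processed), `outliers` (flagged ids),
#'   `surrogate_count`, and `model` (the covariate model used).
#' @export
preprocess_pipeline <- function(ds, cfg = analysis_config(),
                                platform = c("microarray", "rnaseq"),
                                seed = cfg$seed,
                                covariate_terms = c("age_days", "pmi_hours",
                                                    "rin", "ph", "batch")) {
  platform <- match.arg(platform)
  if (platform == "microarray") {
    ds <- filter_rin(ds, "donor_fraction", cfg)
    ds <- log2_transform(ds, offset = 0)
  } else {
    ds <- filter_rin(ds, "sample_threshold", cfg)
    ds <- filter_rpkm(ds, cfg)
    ds <- log2_transform(ds, offset = 1)
  }
  ds <- filter_age_and_autosomes(ds, cfg = cfg)
  ds <- quantile_normalize(ds)
  ds <- collapse_replicates(ds)
  if (!is.null(ds$samples$ph) && any(!is.na(ds$samples$ph)))
    ds <- impute_ph(ds)
  model0 <- covariate_model(ds$samples, terms = covariate_terms)
  k <- cfg$surrogate_count %||%
    estimate_surrogate_count(ds$values, model0, cfg, seed = seed)
  sv <- surrogate_values(ds$values, model0, k)
  model <- covariate_model(ds$samples, terms = covariate_terms,
                           surrogates = sv)
  ds <- residualize(ds, model)
  out <- detect_outliers(ds, cfg)
  list(dataset = out$dataset, outliers = out$flagged,
       surrogate_count = k, model = model)
}
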
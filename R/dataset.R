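#' Construct an expression dataset
#'
#' The central container: a gene x sample matrix together with gene
#' annotation, sample metadata, the declared value scale, and an ordered log
#' of applied transformations. Invariants checked here: dimensions match,
#' sample ids unique, gene ids unique, metadata fields valid.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param genes Data frame with at least `gene_id`; optionally `symbol`,
#'   `chromosome` (one of "1".."22","X","Y","MT"), `start`, `end`
#'   (1-based inclusive bp).
#' @param samples Data frame of sample records with columns `sample_id`,
#'   `donor_id`, `sex` ("M"/"F"), `age_days` (> 0, days post-conception),
#'   `region` (one of the 16 codes), `rin` in [0,10]; optionally
#'   `pmi_hours`, `ph`, `batch` (NA allowed for these three).
#' @param scale Declared value scale, e.g. `"intensity"`, `"rpkm"`,
#'   `"log2"`, `"residual"`.
#' @param transform_log Character vector of operation labels already applied.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, genes, samples, scale = "intensity",
                               transform_log = character()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(values) != nrow(genes))
    stop("gene table and matrix row count differ", call. = FALSE)
  if (ncol(values) != nrow(samples))
    stop("sample table and matrix column count differ", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "),
         call. = FALSE)
  validate_sample_records(samples)
  if (!is.null(genes$chromosome)) validate_gene_annotation(genes)
  rownames(values) <- genes$gene_id
  colnames(values) <- samples$sample_id
  structure(list(values = values, genes = genes, samples = samples,
                 scale = scale, transform_log = as.character(transform_log)),
            class = "expression_dataset")
}

CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")
AUTOSOMES <- as.character(1:22)

validate_sample_records <- function(samples) {
  req <- c("sample_id", "donor_id", "sex", "age_days", "region", "rin")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(samples$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  bad <- setdiff(unique(samples$region), REGION_CODES)
  if (length(bad))
    stop("unknown region code: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(is.na(samples$age_days)) || any(samples$age_days <= 0))
    stop("age_days must be positive and non-missing", call. = FALSE)
  if (any(is.na(samples$rin)) || any(samples$rin < 0 | samples$rin > 10))
    stop("rin must be in [0, 10] and non-missing", call. = FALSE)
  if (!is.null(samples$pmi_hours) &&
      any(!is.na(samples$pmi_hours) & samples$pmi_hours < 0))
    stop("pmi_hours must be >= 0 where present", call. = FALSE)
  invisible(samples)
}

validate_gene_annotation <- function(genes) {
  ann <- !is.na(genes$chromosome)
  bad <- setdiff(unique(genes$chromosome[ann]), CHROMOSOMES)
  if (length(bad))
    stop("unknown chromosome: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(genes$start) && !is.null(genes$end)) {
    pos <- ann & !is.na(genes$start) & !is.na(genes$end)
    if (any(genes$start[pos] > genes$end[pos]))
      stop("gene start must be <= end", call. = FALSE)
  }
  invisible(genes)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", length(unique(x$samples$donor_id)), " donors; ",
      sum(x$samples$sex == "M"), " M / ", sum(x$samples$sex == "F"),
      " F samples)\n", sep = "")
  cat("  scale: ", x$scale, "\n", sep = "")
  if (length(x$transform_log))
    cat("  transforms: ", paste(x$transform_log, collapse = " -> "), "\n",
        sep = "")
  invisible(x)
}

#' Subset an expression dataset by samples
#' @param ds An `expression_dataset`.
#' @param sample_ids Sample ids to keep, in dataset order.
#' @return The reduced dataset.
#' @export
subset_samples <- function(ds, sample_ids) {
  keep <- ds$samples$sample_id %in% sample_ids
  ds$values <- ds$values[, keep, drop = FALSE]
  ds$samples <- ds$samples[keep, , drop = FALSE]
  rownames(ds$samples) <- NULL
  ds
}

#' Subset an expression dataset by genes
#' @param ds An `expression_dataset`.
#' @param gene_ids Gene ids to keep, in dataset order.
#' @return The reduced dataset.
#' @export
subset_genes <- function(ds, gene_ids) {
  keep <- ds$genes$gene_id %in% gene_ids
  ds$values <- ds$values[keep, , drop = FALSE]
  ds$genes <- ds$genes[keep, , drop = FALSE]
  rownames(ds$genes) <- NULL
  ds
}

#' Attach gene annotation to a dataset
#'
#' Joins an annotation table onto the dataset's gene list by `gene_id`.
#' Genes without annotation keep NA coordinates and are dropped later by
#' [filter_age_and_autosomes()] with a logged count.
#'
#' @param ds An `expression_dataset`.
#' @param annotation Data frame with `gene_id`, `chromosome`, `start`, `end`
#'   and optionally `symbol`.
#' @return The dataset with annotation columns filled in.
#' @export
attach_annotation <- function(ds, annotation) {
  validate_gene_annotation(annotation)
  m <- match(ds$genes$gene_id, annotation$gene_id)
  for (col in c("symbol", "chromosome", "start", "end"))
    if (!is.null(annotation[[col]]))
      ds$genes[[col]] <- annotation[[col]][m]
  ds
}

#' Record an applied transform, refusing duplicates
#' @noRd
log_transform <- function(ds, label) {
  if (label %in% ds$transform_log)
    stop("operation '", label, "' was already applied (transform log: ",
         paste(ds$transform_log, collapse = " -> "), ")", call. = FALSE)
  ds$transform_log <- c(ds$transform_log, label)
  ds
}
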
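#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and a
#' fully numeric body. Gene order is preserved; duplicate ids and
#' missing or non-numeric cells are rejected with coordinates.
#'
#' @param path TSV file path.
#' @param scale_label Declared scale of the values (e.g. "rpkm",
#'   "intensity").
#' @return An `expression_dataset` carrying values only: annotation and
#'   metadata are attached separately ([attach_annotation()],
#'   [attach_metadata()]).
#' @export
read_expression_matrix <- function(path, scale_label = "intensity") {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2L) stop("expression matrix needs at least one sample column",
                           call. = FALSE)
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  body <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(values) | is.na(body) | body == "", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values,
                 genes = data.frame(gene_id = gene_ids,
                                    stringsAsFactors = FALSE),
                 samples = data.frame(sample_id = sample_ids,
                                      stringsAsFactors = FALSE),
                 scale = scale_label, transform_log = character()),
            class = "expression_dataset")
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: header of sample ids, first column
#' `gene_id`, full numeric precision so a round trip reproduces values.
#'
#' @param ds An `expression_dataset` (or anything with `$values`).
#' @param path Output TSV path.
#' @export
write_expression_matrix <- function(ds, path) {
  df <- data.frame(gene_id = rownames(ds$values),
                   format(ds$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(ds$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns: sample_id, donor_id, sex, age_value, age_unit
#' (pcw|days|months|years), region, rin, pmi_hours, ph, batch. Ages are
#' normalized to days post-conception; empty ph/pmi/batch cells become NA.
#'
#' @param path TSV file path.
#' @return Data frame of sample records (one row per sample).
#' @export
read_sample_metadata <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("sample_id", "donor_id", "sex", "age_value", "age_unit",
           "region", "rin")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  opt_num <- function(x) {
    if (is.null(x)) return(rep(NA_real_, nrow(raw)))
    x[x == ""] <- NA_character_
    num(x)
  }
  samples <- data.frame(
    sample_id = raw$sample_id,
    donor_id = raw$donor_id,
    sex = raw$sex,
    age_days = normalize_age(num(raw$age_value), raw$age_unit),
    region = raw$region,
    rin = num(raw$rin),
    pmi_hours = opt_num(raw$pmi_hours),
    ph = opt_num(raw$ph),
    batch = if (is.null(raw$batch)) NA_character_ else
      ifelse(raw$batch == "", NA_character_, raw$batch),
    stringsAsFactors = FALSE
  )
  validate_sample_records(samples)
  samples
}

#' Attach sample metadata to a dataset
#'
#' @param ds An `expression_dataset` holding values only.
#' @param metadata Sample records as from [read_sample_metadata()]; must
#'   cover every matrix column.
#' @return The dataset with full metadata, columns in matrix order.
#' @export
attach_metadata <- function(ds, metadata) {
  m <- match(ds$samples$sample_id, metadata$sample_id)
  if (anyNA(m))
    stop("metadata missing for samples: ",
         paste(ds$samples$sample_id[is.na(m)], collapse = ", "),
         call. = FALSE)
  expression_dataset(ds$values, ds$genes, metadata[m, , drop = FALSE],
                     scale = ds$scale, transform_log = ds$transform_log)
}

#' Read gene annotation from TSV
#'
#' Columns: gene_id, symbol (optional), chromosome, start, end (1-based
#' inclusive bp).
#'
#' @param path TSV file path.
#' @return Validated annotation data frame.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ann$chromosome <- as.character(ann$chromosome)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation", call. = FALSE)
  validate_gene_annotation(ann)
  ann
}

#' Read GWAS risk loci from TSV
#'
#' One row per index variant with columns locus_id, chromosome, start, end,
#' position, p_value. Rows sharing a locus_id are grouped into one locus
#' whose index variants are sorted by ascending association p-value.
#'
#' @param path TSV file path.
#' @return List of risk-locus records, each a list with `locus_id`,
#'   `chromosome`, `start`, `end` and a `variants` data frame
#'   (`position`, `p_value`).
#' @export
read_risk_loci <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("risk locus file is empty: ", path, call. = FALSE)
    return(list())
  }
  req <- c("locus_id", "chromosome", "start", "end", "position", "p_value")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("locus table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  raw$chromosome <- as.character(raw$chromosome)
  loci <- lapply(split(raw, raw$locus_id), function(g) {
    if (length(unique(g$chromosome)) != 1L ||
        length(unique(g$start)) != 1L || length(unique(g$end)) != 1L)
      stop("inconsistent coordinates for locus ", g$locus_id[1], call. = FALSE)
    if (any(is.na(g$position)) || any(is.na(g$p_value)))
      stop("locus ", g$locus_id[1], " has an index variant without position",
           " or p-value", call. = FALSE)
    variants <- g[order(g$p_value), c("position", "p_value")]
    rownames(variants) <- NULL
    list(locus_id = g$locus_id[1], chromosome = g$chromosome[1],
         start = g$start[1], end = g$end[1], variants = variants)
  })
  unname(loci[order(vapply(loci, `[[`, "", "locus_id"))])
}

#' Read a plain gene list (one id per line)
#' @param path File path.
#' @return Character vector of unique, non-empty gene ids in file order.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  unique(ids[ids != ""])
}

#' Write a result table with a machine-readable run manifest
#'
#' Tabular results are written as TSV; alongside it a JSON manifest records
#' the configuration, master seed, package and R versions, and the dataset's
#' transform log, so any run can be reproduced exactly.
#'
#' @param results A data frame, or a result object with an
#'   [as_results_table()] method (similarity, sex-difference, co-expression
#'   and variability results all have one).
#' @param dir Output directory (created if needed).
#' @param name Basename for `<name>.tsv` and `<name>_manifest.json`.
#' @param config The `analysis_config` used (echoed into the manifest).
#' @param seed Master seed of the run.
#' @param transform_log Transform log of the dataset analyzed.
#' @return Invisibly, the TSV path.
#' @export
write_results <- function(results, dir, name = "results", config = NULL,
                          seed = NULL, transform_log = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- as_results_table(results)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  ok <- tryCatch({
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", tsv, ": ", conditionMessage(e),
                              call. = FALSE))
  manifest <- list(
    name = name,
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    transform_log = transform_log,
    package_version = as.character(utils::packageVersion("brainvar")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(tsv)
}

#' Coerce result objects to a flat table
#' @param x A result object.
#' @return A data frame.
#' @export
as_results_table <- function(x) UseMethod("as_results_table")

#' @export
as_results_table.data.frame <- function(x) x

#' @export
as_results_table.similarity_result <- function(x) {
  data.frame(cluster = x$cluster_id, bin = x$bin_index, sex = x$sex,
             estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
             n_donors = x$n_donors, stringsAsFactors = FALSE)
}

#' @export
as_results_table.sex_difference_result <- function(x) {
  data.frame(cluster = x$cluster_id, mean_difference = x$mean_difference,
             empirical_p = x$empirical_p, p_lt = x$p_lt %||% NA_real_,
             corrected_p = x$corrected_p, n_permutations = x$n_permutations,
             included_bins = paste(x$included_bins, collapse = ","),
             stringsAsFactors = FALSE)
}

#' @export
as_results_table.coexpression_result <- function(x) {
  data.frame(cluster = x$cluster_id, bin = x$bin_index,
             risk_set = x$risk_set_label, rho = x$rho,
             null_mean = x$null_mean, null_sd = x$null_sd,
             empirical_p = x$empirical_p, corrected_p = x$corrected_p,
             n_variability_genes = x$n_variability_genes,
             n_risk_genes = x$n_risk_genes, stringsAsFactors = FALSE)
}

#' @export
as_results_table.variability_gene_set <- function(x) {
  data.frame(cluster = attr(x, "cluster_id") %||% NA_integer_,
             bin = attr(x, "bin_index") %||% NA_integer_,
             rank = seq_len(nrow(x)), gene_id = x$gene_id,
             sd_ratio = x$sd_ratio, male_sd = x$male_sd,
             female_sd = x$female_sd, stringsAsFactors = FALSE)
}

#' @export
as_results_table.list <- function(x) {
  do.call(rbind, lapply(x, as_results_table))
}
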
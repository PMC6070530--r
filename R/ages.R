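#' The 16 BrainSpan brain-region codes
#'
#' Neocortical areas (V1C, ITC, IPC, A1C, STC, M1C, S1C, VFC, MFC, DFC, OFC),
#' striatum (STR), hippocampus (HIP), amygdala (AMY), mediodorsal thalamus
#' (MD) and cerebellar cortex (CBC).
#'
#' @export
REGION_CODES <- c("V1C", "ITC", "IPC", "A1C", "STC",
                  "M1C", "S1C", "VFC", "MFC", "DFC", "OFC",
                  "STR", "HIP", "AMY", "MD", "CBC")

#' Default regional clusters
#'
#' Four groups of the 16 region codes aggregated by fetal expression
#' similarity: (1) V1C-STC, (2) prefrontal / primary motor-somatosensory
#' cortex (PFC-MSC), (3) STR-HIP-AMY, (4) MD-CBC. Together they partition
#' the 16 codes.
#'
#' @return A data frame with columns `cluster_id`, `label` and a list column
#'   `member_regions`.
#' @export
default_region_clusters <- function() {
  data.frame(
    cluster_id = 1:4,
    label = c("V1C-STC", "PFC-MSC", "STR-HIP-AMY", "MD-CBC"),
    member_regions = I(list(
      c("V1C", "ITC", "IPC", "A1C", "STC"),
      c("M1C", "S1C", "VFC", "MFC", "DFC", "OFC"),
      c("STR", "HIP", "AMY"),
      c("MD", "CBC")
    )),
    stringsAsFactors = FALSE
  )
}

#' Convert an age to days post-conception
#'
#' All ages are stored on a single monotone axis of days post-conception.
#' Prenatal ages arrive in post-conceptional weeks (pcw); postnatal ages are
#' offset by 280 days (40 gestational weeks), with months taken as 30.44 days
#' and years as 365.25 days.
#'
#' @param value Positive age value (vectorized).
#' @param unit One of `"pcw"`, `"days"`, `"months"`, `"years"` (recycled).
#' @return Age in days post-conception.
#' @examples
#' normalize_age(6, "pcw")     # 42
#' normalize_age(0.5, "years") # 462.625
#' @export
normalize_age <- function(value, unit) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("age values must be positive and finite", call. = FALSE)
  unit <- rep_len(as.character(unit), length(value))
  bad <- setdiff(unique(unit), c("pcw", "days", "months", "years"))
  if (length(bad))
    stop("unknown age unit: ", paste(bad, collapse = ", "), call. = FALSE)
  ifelse(unit == "pcw", value * 7,
    ifelse(unit == "days", 280 + value,
      ifelse(unit == "months", 280 + value * 30.44,
        280 + value * 365.25)))
}

#' Default 13-period developmental age table
#'
#' A stand-in period table spanning 6 post-conceptional weeks to 40 years,
#' reconstructed from the published age-bin ranges (bin 1 covers 6-13 PCW,
#' bin 2 covers 9-16 PCW, bin 8 covers 4 months-4 years, bin 9 covers
#' 10 months-11 years, bin 10 covers 2-19 years under 3-period windows).
#' It is a stand-in, not the original cohort's period table, and any table
#' satisfying [validate_period_table()] may be supplied instead.
#'
#' Boundaries are in days post-conception; `lower_days` inclusive,
#' `upper_days` exclusive.
#'
#' @return Data frame with columns `index`, `lower_days`, `upper_days`.
#' @export
default_period_table <- function() {
  pcw <- function(w) w * 7
  mo <- function(m) 280 + m * 30.44
  yr <- function(y) 280 + y * 365.25
  lower <- c(pcw(6), pcw(9), pcw(10), pcw(13), pcw(16), pcw(24),
             pcw(38), mo(4), mo(10), yr(2), yr(4), yr(11), yr(19))
  upper <- c(lower[-1], yr(40) + 1)
  data.frame(index = seq_along(lower), lower_days = lower, upper_days = upper)
}

#' Validate a period table
#'
#' Periods must be contiguous, non-overlapping and strictly ascending.
#'
#' @param periods Data frame with `index`, `lower_days`, `upper_days`.
#' @return The table, invisibly, or an error.
#' @export
validate_period_table <- function(periods) {
  stopifnot(all(c("index", "lower_days", "upper_days") %in% names(periods)))
  periods <- periods[order(periods$index), ]
  if (!identical(as.integer(periods$index), seq_len(nrow(periods))))
    stop("period indices must be 1..P", call. = FALSE)
  if (any(periods$lower_days >= periods$upper_days))
    stop("each period needs lower_days < upper_days", call. = FALSE)
  if (nrow(periods) > 1 &&
      any(abs(periods$lower_days[-1] - periods$upper_days[-nrow(periods)]) > 1e-9))
    stop("periods must be contiguous", call. = FALSE)
  invisible(periods)
}

#' Map ages to developmental periods
#'
#' @param age_days Ages in days post-conception.
#' @param periods A period table (see [default_period_table()]).
#' @return Integer period index per age; ages outside the table are an error.
#' @export
assign_periods <- function(age_days, periods = default_period_table()) {
  validate_period_table(periods)
  idx <- findInterval(age_days, c(periods$lower_days, periods$upper_days[nrow(periods)]),
                      rightmost.closed = FALSE)
  if (any(idx < 1L) || any(idx > nrow(periods)))
    stop("ages outside the period table: ",
         paste(signif(age_days[idx < 1L | idx > nrow(periods)], 4), collapse = ", "),
         call. = FALSE)
  as.integer(periods$index[idx])
}

#' Build overlapping age-bins from a period table
#'
#' Bins join `width` consecutive periods and slide by one, so P periods give
#' P - width + 1 bins; the default 13 periods and width 3 give 11 bins. A
#' donor whose period falls inside several windows belongs to every one of
#' those bins.
#'
#' @param periods Period table.
#' @param width Number of consecutive periods per bin.
#' @return Data frame with `bin_index` and list column `member_periods`.
#' @export
make_age_bins <- function(periods = default_period_table(), width = 3L) {
  validate_period_table(periods)
  p <- nrow(periods)
  if (width < 1L || width > p)
    stop("bin width must be between 1 and the period count", call. = FALSE)
  n_bins <- p - width + 1L
  data.frame(
    bin_index = seq_len(n_bins),
    member_periods = I(lapply(seq_len(n_bins), function(b) b:(b + width - 1L)))
  )
}

#' Read a period table from TSV
#'
#' Columns `index`, `lower_days`, `upper_days`; validated on read. The
#' packaged stand-in table is at
#' `system.file("extdata", "period_table.tsv", package = "brainvar")`.
#'
#' @param path TSV file path.
#' @return A validated period table.
#' @export
read_period_table <- function(path) {
  periods <- utils::read.delim(path, header = TRUE, sep = "\t")
  validate_period_table(periods)
  periods
}
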
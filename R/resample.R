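#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Every stochastic stage of the pipeline consumes its own derived
#' substream, so results are invariant to the order in which strata or
#' repetitions are evaluated. The derivation is a polynomial string hash of
#' the master seed and the key parts, reduced modulo a 31-bit prime.
#'
#' @param seed Integer master seed.
#' @param ... Key parts (coerced to character) identifying the substream.
#' @return An integer seed in [1, 2^31).
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  p <- 2147483563
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% p
  as.integer(h + 1)
}

sample_one <- function(x) x[sample.int(length(x), 1L)]

#' One three-stage donor-aware resample
#'
#' Produces a per-sex donor and sample selection for a stratum:
#' \enumerate{
#'   \item one sample is selected uniformly per donor (donors visited in
#'     stratum order), neutralizing the non-independence of multiple
#'     samples per donor;
#'   \item per sex (males first, then females), donors are bootstrapped
#'     with replacement and reduced to the unique set, preventing perfect
#'     correlation between multiply-drawn donors;
#'   \item the larger sex's unique set is subsampled without replacement to
#'     the smaller sex's count, so both sexes contribute the same number of
#'     subjects (no random draw occurs when counts already agree).
#' }
#' If either sex retains fewer than 2 unique donors after stage 2 the draw
#' is retried, up to `cfg$resample_max_retries` times, after which `NULL`
#' is returned with a warning.
#'
#' The random-number consumption order stated above is part of the
#' function's contract (one `sample.int` per donor, then one per sex, then
#' at most one subsample), so an independent re-implementation sharing the
#' seed stream reproduces every draw exactly.
#'
#' @param stratum A stratum from [build_strata()].
#' @param sex_assignment Named character vector donor -> "M"/"F"; defaults
#'   to the stratum's true assignment. Permutation tests pass shuffled
#'   labels here.
#' @param cfg An [analysis_config()].
#' @return List with `male_donors`, `female_donors`, `male_samples`,
#'   `female_samples`, or `NULL` when all retries failed.
#' @export
draw_resample <- function(stratum, sex_assignment = NULL,
                          cfg = analysis_config()) {
  if (isTRUE(stratum$excluded))
    stop("stratum (cluster ", stratum$cluster_id, ", bin ",
         stratum$bin_index, ") is excluded", call. = FALSE)
  if (is.null(sex_assignment)) sex_assignment <- stratum$donor_sex
  donors <- stratum$donors
  m_don <- donors[sex_assignment[donors] == "M"]
  f_don <- donors[sex_assignment[donors] == "F"]
  for (attempt in seq_len(cfg$resample_max_retries)) {
    picked <- vapply(stratum$donor_samples,
                     function(ids) ids[sample.int(length(ids), 1L)],
                     character(1))
    m_boot <- unique(m_don[sample.int(length(m_don), length(m_don),
                                      replace = TRUE)])
    f_boot <- unique(f_don[sample.int(length(f_don), length(f_don),
                                      replace = TRUE)])
    if (length(m_boot) < 2L || length(f_boot) < 2L) next
    n_use <- min(length(m_boot), length(f_boot))
    if (length(m_boot) > n_use)
      m_boot <- m_boot[sample.int(length(m_boot), n_use)]
    else if (length(f_boot) > n_use)
      f_boot <- f_boot[sample.int(length(f_boot), n_use)]
    return(list(male_donors = m_boot, female_donors = f_boot,
                male_samples = unname(picked[m_boot]),
                female_samples = unname(picked[f_boot])))
  }
  warning("resample skipped: a sex had < 2 unique donors after ",
          cfg$resample_max_retries, " retries", call. = FALSE)
  NULL
}

#' One male-only resample (stages 1-2)
#'
#' The co-expression analysis runs in males only, so the equal-n
#' subsampling stage is omitted: one sample per male donor, then a donor
#' bootstrap reduced to the unique set. Draws leaving fewer than `min_n`
#' unique donors are retried.
#'
#' @param stratum A stratum from [build_strata()].
#' @param cfg An [analysis_config()].
#' @param min_n Minimum unique male donors per draw.
#' @return List with `male_donors`, `male_samples`, or `NULL`.
#' @export
draw_male_resample <- function(stratum, cfg = analysis_config(), min_n = 3L) {
  m_don <- stratum$donors[stratum$donor_sex[stratum$donors] == "M"]
  if (length(m_don) < min_n)
    stop("stratum has fewer than ", min_n, " male donors", call. = FALSE)
  m_samples <- stratum$donor_samples[m_don]
  for (attempt in seq_len(cfg$resample_max_retries)) {
    picked <- vapply(m_samples,
                     function(ids) ids[sample.int(length(ids), 1L)],
                     character(1))
    m_boot <- unique(m_don[sample.int(length(m_don), length(m_don),
                                      replace = TRUE)])
    if (length(m_boot) < min_n) next
    return(list(male_donors = m_boot, male_samples = unname(picked[m_boot])))
  }
  warning("male resample skipped after ", cfg$resample_max_retries,
          " retries", call. = FALSE)
  NULL
}
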
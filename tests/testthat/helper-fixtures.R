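# Shared fixtures and independent brute-force oracles.

# A minimal expression dataset built by hand (no generator involvement).
tiny_dataset <- function(n_genes = 20, n_donors_per_sex = 3,
                         regions = c("DFC", "MFC"), seed = 42,
                         age_days = 400) {
  set.seed(seed)
  donors <- sprintf("d%02d", seq_len(2 * n_donors_per_sex))
  sex <- rep(c("M", "F"), each = n_donors_per_sex)
  rows <- expand.grid(donor = donors, region = regions,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0(rows$donor, "_", rows$region),
    donor_id = rows$donor,
    sex = sex[match(rows$donor, donors)],
    age_days = age_days + seq_len(nrow(rows)) * 0.5,
    region = rows$region,
    rin = 8.5, pmi_hours = 10, ph = 6.5, batch = "b1",
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  values <- matrix(rnorm(n_genes * nrow(samples), mean = 5),
                   nrow = n_genes,
                   dimnames = list(genes$gene_id, samples$sample_id))
  expression_dataset(values, genes, samples, scale = "residual")
}

tiny_stratum <- function(ds, cluster_id = 2L, bin_index = 1L) {
  s <- ds$samples
  donors <- unique(s$donor_id)
  donor_samples <- split(s$sample_id, factor(s$donor_id, levels = donors))
  donor_sex <- vapply(donor_samples, function(ids)
    s$sex[match(ids[1], s$sample_id)], character(1))
  structure(list(cluster_id = cluster_id, bin_index = bin_index,
                 sample_ids = s$sample_id, donors = donors,
                 donor_samples = donor_samples, donor_sex = donor_sex,
                 n_male_donors = sum(donor_sex == "M"),
                 n_female_donors = sum(donor_sex == "F"),
                 excluded = FALSE),
            class = "stratum")
}

# Plain-loop Pearson correlation, written independently of the package.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_mean_pairwise <- function(mat) {
  n <- ncol(mat)
  acc <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    acc <- acc + oracle_pearson(mat[, i], mat[, j])
    cnt <- cnt + 1
  }
  acc / cnt
}

# Brute-force re-implementation of the three-stage resampling estimators,
# consuming the same documented random-number stream: per draw, one
# sample.int per donor in stratum order, one bootstrap per sex (M then F),
# then at most one subsample of the larger sex.
oracle_draw <- function(stratum, max_retries = 10L) {
  donors <- stratum$donors
  m_don <- donors[stratum$donor_sex[donors] == "M"]
  f_don <- donors[stratum$donor_sex[donors] == "F"]
  for (a in seq_len(max_retries)) {
    picked <- character(length(donors))
    names(picked) <- donors
    for (i in seq_along(donors)) {
      ids <- stratum$donor_samples[[i]]
      picked[i] <- ids[sample.int(length(ids), 1L)]
    }
    mb <- unique(m_don[sample.int(length(m_don), length(m_don), replace = TRUE)])
    fb <- unique(f_don[sample.int(length(f_don), length(f_don), replace = TRUE)])
    if (length(mb) < 2 || length(fb) < 2) next
    n_use <- min(length(mb), length(fb))
    if (length(mb) > n_use) mb <- mb[sample.int(length(mb), n_use)]
    else if (length(fb) > n_use) fb <- fb[sample.int(length(fb), n_use)]
    return(list(m = unname(picked[mb]), f = unname(picked[fb])))
  }
  NULL
}

oracle_similarity <- function(stratum, values, n_resamples, seed) {
  set.seed(seed)
  em <- ef <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    d <- oracle_draw(stratum)
    em[r] <- oracle_mean_pairwise(values[, d$m, drop = FALSE])
    ef[r] <- oracle_mean_pairwise(values[, d$f, drop = FALSE])
  }
  list(male = mean(em), female = mean(ef),
       male_ci = unname(quantile(em, c(0.025, 0.975))),
       female_ci = unname(quantile(ef, c(0.025, 0.975))))
}

oracle_gene_sd <- function(stratum, values, n_resamples, seed) {
  set.seed(seed)
  am <- af <- numeric(nrow(values))
  for (r in seq_len(n_resamples)) {
    d <- oracle_draw(stratum)
    for (g in seq_len(nrow(values))) {
      am[g] <- am[g] + sd(values[g, d$m])
      af[g] <- af[g] + sd(values[g, d$f])
    }
  }
  list(male = am / n_resamples, female = af / n_resamples)
}

oracle_median_cross_cor <- function(values, set_a, set_b) {
  out <- c()
  for (a in set_a) for (b in set_b) {
    if (a == b) next
    out <- c(out, oracle_pearson(values[a, ], values[b, ]))
  }
  median(out)
}

# Small study used by several coexpression tests.
small_study <- function(seed = 5, rho = 0.3, lambda = 2, n_genes = 300) {
  params <- simulation_params(
    n_genes = n_genes, periods = 2, donors_per_period = 5,
    regions = c("DFC", "MFC", "VFC"), lambda = lambda, rho_star = rho,
    n_risk_genes = 15, replicate_prob = 0, frac_x_genes = 0.04)
  simulate_study(params, seed)
}
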
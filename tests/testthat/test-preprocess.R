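make_rin_dataset <- function(rins, donors, regions = NULL) {
  n <- length(rins)
  if (is.null(regions)) regions <- REGION_CODES[seq_len(n)]
  samples <- data.frame(
    sample_id = sprintf("s%d", seq_len(n)), donor_id = donors,
    sex = "M", age_days = 500, region = regions, rin = rins,
    pmi_hours = 10, ph = 6.5, batch = "b1", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  expression_dataset(matrix(1:(2 * n), 2, n), genes, samples)
}

test_that("donor-fraction RIN rule keeps the 25% boundary and is idempotent", {
  ds <- make_rin_dataset(c(7.0, 8, 8, 8), rep("d1", 4))
  kept <- filter_rin(ds, "donor_fraction")
  expect_equal(ncol(kept$values), 4L)  # fraction exactly 0.25, not > 0.25

  ds2 <- make_rin_dataset(c(7.0, 8), rep("d1", 2))
  expect_equal(ncol(filter_rin(ds2, "donor_fraction")$values), 0L)

  twice <- filter_rin(filter_rin(ds, "donor_fraction"), "donor_fraction")
  expect_equal(twice$values, kept$values)
})

test_that("sample-threshold RIN rule removes RIN <= 7.5", {
  ds <- make_rin_dataset(c(7.5, 7.51, 9), c("d1", "d2", "d3"))
  kept <- filter_rin(ds, "sample_threshold")
  expect_setequal(kept$samples$sample_id, c("s2", "s3"))
})

test_that("age filter keeps exactly-40-year donors; autosome filter drops X", {
  ds <- tiny_dataset(n_genes = 6, n_donors_per_sex = 2)
  ds$samples$age_days[1:2] <- normalize_age(40, "years")       # kept
  ds$samples$age_days[3] <- normalize_age(40, "years") + 1     # dropped
  ann <- data.frame(gene_id = ds$genes$gene_id,
                    chromosome = c("1", "2", "X", "22", "Y", "3"),
                    start = 1, end = 10, stringsAsFactors = FALSE)
  out <- filter_age_and_autosomes(ds, ann)
  expect_false("s3" %in% out$samples$sample_id ||
                 ds$samples$sample_id[3] %in% out$samples$sample_id)
  expect_true(all(ds$samples$sample_id[1:2] %in% out$samples$sample_id))
  expect_setequal(out$genes$gene_id, ds$genes$gene_id[c(1, 2, 4, 6)])
})

test_that("RPKM filter uses strict more-than-50% in either sex, pre-log only", {
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:8), donor_id = sprintf("d%d", 1:8),
    sex = rep(c("M", "F"), each = 4), age_days = 500,
    region = REGION_CODES[1:8], rin = 9, pmi_hours = 10, ph = 6.5,
    batch = "b1", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("lowM", "half", "high"))
  values <- rbind(c(0.1, 0.2, 0.3, 2, 5, 5, 5, 5),   # low in 3/4 males
                  c(0.5, 0.5, 2, 2, 0.5, 0.5, 2, 2), # low in exactly half
                  matrix(5, 1, 8))
  ds <- expression_dataset(values, genes, samples, scale = "rpkm")
  out <- filter_rpkm(ds)
  expect_setequal(out$genes$gene_id, c("half", "high"))
  expect_error(filter_rpkm(log2_transform(ds)), "pre-log")
})

test_that("log2 transform applies the offset and refuses double application", {
  ds <- make_rin_dataset(c(8, 9), c("d1", "d2"))
  ds$values[] <- c(3, 0, 1, 7)
  out <- log2_transform(ds, offset = 1)
  expect_equal(out$values[1, 1], 2)
  expect_equal(out$values[2, 1], 0)
  expect_error(log2_transform(out), "already applied")
})

test_that("quantile normalization equalizes column multisets (hand case and
           random property)", {
  ds <- make_rin_dataset(c(8, 9), c("d1", "d2"))
  g3 <- expression_dataset(
    matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
           dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))),
    data.frame(gene_id = c("g1", "g2", "g3")),
    make_rin_dataset(c(8, 9), c("d1", "d2"))$samples)
  out <- quantile_normalize(g3)
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))

  set.seed(11)
  for (rep_i in 1:5) {
    n <- sample(5:30, 1)
    m <- sample(3:6, 1)
    samples <- data.frame(
      sample_id = sprintf("s%d", 1:m), donor_id = sprintf("d%d", 1:m),
      sex = "F", age_days = 300, region = REGION_CODES[1:m], rin = 9,
      pmi_hours = 5, ph = 6.5, batch = "b1")
    ds_r <- expression_dataset(
      matrix(rnorm(n * m), n, m), data.frame(gene_id = sprintf("g%d", 1:n)),
      samples)
    qn <- quantile_normalize(ds_r)$values
    ref <- sort(qn[, 1])
    for (j in 2:m) expect_equal(unname(sort(qn[, j])), unname(ref))
  }
})

test_that("replicate collapsing takes per-gene medians per donor-region", {
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:4),
    donor_id = c("d1", "d1", "d1", "d2"),
    sex = c("M", "M", "M", "F"), age_days = 500,
    region = c("DFC", "DFC", "DFC", "DFC"),
    rin = c(8, 9, 9.5, 9), pmi_hours = 10, ph = 6.5, batch = "b1")
  genes <- data.frame(gene_id = c("g1", "g2"))
  values <- rbind(c(1, 2, 10, 7), c(1, 3, 100, 8))
  ds <- expression_dataset(values, genes, samples)
  out <- collapse_replicates(ds)
  expect_equal(ncol(out$values), 2L)
  expect_equal(unname(out$values[, 1]), c(2, 3))   # medians of 3 replicates
  expect_equal(out$samples$rin[1], 9)              # median rin
  expect_equal(collapse_replicates(out)$values, out$values)  # idempotent

  two <- subset_samples(ds, c("s1", "s2"))
  expect_equal(unname(collapse_replicates(two)$values[, 1]), c(1.5, 2))
})

test_that("pH imputation fills the observed mean and errors when all missing", {
  ds <- make_rin_dataset(c(8, 9, 9), c("d1", "d2", "d3"))
  ds$samples$ph <- c(6.0, NA, 7.0)
  expect_equal(impute_ph(ds)$samples$ph, c(6.0, 6.5, 7.0))
  ds$samples$ph <- c(6, 6.5, 7)
  expect_equal(impute_ph(ds)$samples$ph, c(6, 6.5, 7))
  ds$samples$ph <- NA_real_
  expect_error(impute_ph(ds), "drop pH")
})

test_that("surrogate-count estimation finds planted factors and not noise", {
  make_model <- function(n_samples) {
    samples <- data.frame(
      sample_id = sprintf("s%d", 1:n_samples),
      donor_id = sprintf("d%d", 1:n_samples),
      sex = rep(c("M", "F"), length.out = n_samples),
      age_days = seq(300, 900, length.out = n_samples),
      region = "DFC", rin = runif(n_samples, 8, 10),
      pmi_hours = runif(n_samples, 5, 20), ph = rnorm(n_samples, 6.5, 0.2),
      batch = "b1")
    covariate_model(samples, terms = c("age_days", "pmi_hours", "rin", "ph"))
  }
  set.seed(202)
  model <- make_model(40)
  noise <- matrix(rnorm(200 * 40), 200, 40)
  one <- noise + outer(rnorm(200, 0, 3), rnorm(40))
  two <- one + outer(rnorm(200, 0, 3), rnorm(40))
  expect_equal(estimate_surrogate_count(noise, model, seed = 1), 0L)
  expect_equal(estimate_surrogate_count(one, model, seed = 1), 1L)
  expect_equal(estimate_surrogate_count(two, model, seed = 1), 2L)
})

test_that("surrogate-count estimation is stable across seeds at strong
           loading and calibrated on pure noise", {
  set.seed(77)
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:36), donor_id = sprintf("d%d", 1:36),
    sex = rep(c("M", "F"), 18), age_days = seq(300, 900, length.out = 36),
    region = "DFC", rin = runif(36, 8, 10), pmi_hours = 10,
    ph = rnorm(36, 6.5, 0.2), batch = "b1")
  model <- covariate_model(samples, terms = c("age_days", "rin", "ph"))
  hits <- zero_ok <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    noise <- matrix(rnorm(150 * 36), 150, 36)
    planted <- noise + outer(rnorm(150, 0, 3), rnorm(36))
    if (estimate_surrogate_count(planted, model, seed = s) == 1L)
      hits <- hits + 1L
    if (estimate_surrogate_count(noise, model, seed = s) == 0L)
      zero_ok <- zero_ok + 1L
  }
  expect_gte(hits, 0.9 * n_seeds)
  expect_gte(zero_ok, 0.95 * n_seeds)
})

test_that("residualization removes modeled covariates but never sex", {
  set.seed(303)
  n <- 30
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:n), donor_id = sprintf("d%d", 1:n),
    sex = rep(c("M", "F"), n / 2), age_days = seq(100, 5000, length.out = n),
    region = "DFC", rin = runif(n, 8, 10), pmi_hours = runif(n, 5, 25),
    ph = rnorm(n, 6.5, 0.2), batch = rep(c("b1", "b2"), each = n / 2))
  genes <- data.frame(gene_id = sprintf("g%d", 1:40))
  shift <- 1.5
  values <- matrix(rnorm(40 * n), 40, n)
  values[1, ] <- 3 * samples$age_days / 1000          # exactly linear in age
  values[5, ] <- values[5, ] + shift * (samples$sex == "M")
  ds <- expression_dataset(values, genes, samples, scale = "log2")
  model <- covariate_model(samples)
  out <- residualize(ds, model)

  expect_lt(max(abs(out$values[1, ])), 1e-8)
  m_mean <- rowMeans(out$values[, samples$sex == "M"])
  f_mean <- rowMeans(out$values[, samples$sex == "F"])
  expect_equal(unname(m_mean[5] - f_mean[5]), shift, tolerance = 0.35)

  # residuals orthogonal to every design column (standardized)
  for (j in seq_len(ncol(model$null_design))) {
    col <- model$null_design[, j]
    if (sd(col) > 0) col <- (col - mean(col)) / sd(col)
    expect_lt(max(abs(out$values %*% col)) / ncol(out$values), 1e-6)
  }

  # collinear design is rejected with the offending term named
  samples2 <- samples
  samples2$pmi_hours <- samples2$age_days * 2
  expect_error(residualize(ds, covariate_model(samples2)), "collinear")
})

test_that("per-sex PCA outlier rule flags a planted outlier and spares
           clean data", {
  set.seed(404)
  n_per_sex <- 12
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:(2 * n_per_sex)),
    donor_id = sprintf("d%d", 1:(2 * n_per_sex)),
    sex = rep(c("M", "F"), each = n_per_sex), age_days = 500,
    region = "DFC", rin = 9, pmi_hours = 10, ph = 6.5, batch = "b1")
  genes <- data.frame(gene_id = sprintf("g%d", 1:100))
  values <- matrix(rnorm(100 * 2 * n_per_sex), 100)
  direction <- rnorm(100)
  values[, 3] <- values[, 3] + 10 * direction   # male sample s3 displaced
  ds <- expression_dataset(values, genes, samples, scale = "residual")
  out <- detect_outliers(ds)
  expect_identical(out$flagged, "s3")
  expect_false("s3" %in% out$dataset$samples$sample_id)

  clean <- expression_dataset(matrix(rnorm(100 * 2 * n_per_sex), 100),
                              genes, samples, scale = "residual")
  expect_lte(length(detect_outliers(clean)$flagged), 2L)

  # a duplicate of the mean profile is never flagged
  dup <- clean
  dup$values[, 5] <- rowMeans(dup$values[, dup$samples$sex == "M"])
  expect_false("s5" %in% detect_outliers(dup)$flagged)

  few <- subset_samples(ds, samples$sample_id[c(1:3, 13:24)])
  expect_warning(detect_outliers(few), "fewer than 4 M")
})

test_that("the pipeline records its stage order in the transform log", {
  sim <- small_study(seed = 9)
  cfg <- analysis_config(surrogate_count = 0)
  pp <- preprocess_pipeline(sim$dataset, cfg, "microarray")
  expect_identical(pp$dataset$transform_log,
                   c("filter_rin:donor_fraction", "log2_transform",
                     "filter_age_and_autosomes", "quantile_normalize",
                     "collapse_replicates", "impute_ph", "residualize",
                     "detect_outliers"))
  expect_identical(pp$dataset$scale, "residual")
  expect_false(any(pp$dataset$genes$chromosome == "X"))
  # replicates collapsed: one sample per donor-region
  key <- paste(pp$dataset$samples$donor_id, pp$dataset$samples$region)
  expect_false(anyDuplicated(key) > 0)
})
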
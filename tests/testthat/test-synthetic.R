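test_that("cohort generation produces the configured design", {
  params <- simulation_params(n_genes = 50, periods = 5,
                              donors_per_period = 3,
                              regions = c("DFC", "MFC", "V1C", "HIP"),
                              replicate_prob = 0)
  cohort <- generate_cohort(params, seed = 2)
  expect_equal(nrow(cohort), 24L)  # 3 donors x 2 sexes x 4 regions
  expect_equal(length(unique(cohort$donor_id)), 6L)
  expect_setequal(unique(cohort$region), c("DFC", "MFC", "V1C", "HIP"))
  expect_true(all(table(cohort$donor_id) == 4L))
  # ages live inside period 5
  pt <- default_period_table()
  expect_true(all(cohort$age_days >= pt$lower_days[5] &
                    cohort$age_days < pt$upper_days[5]))
  # per-period donor counts match the spec exactly
  params2 <- simulation_params(n_genes = 50, periods = c(2, 9),
                               donors_per_period = c(2, 4),
                               regions = "DFC", replicate_prob = 0)
  cohort2 <- generate_cohort(params2, seed = 3)
  periods <- assign_periods(cohort2$age_days)
  donors_by_period <- tapply(cohort2$donor_id, periods,
                             function(x) length(unique(x)))
  expect_equal(as.integer(donors_by_period), c(4L, 8L))  # per sex x 2
})

test_that("replicates appear and collapse away", {
  params <- simulation_params(n_genes = 30, periods = 3,
                              donors_per_period = 4, regions = c("DFC"),
                              replicate_prob = 1, n_risk_genes = 3)
  sim <- simulate_study(params, 4)
  expect_equal(ncol(sim$dataset$values), 16L)  # every donor-region doubled
  collapsed <- collapse_replicates(sim$dataset)
  expect_equal(ncol(collapsed$values), 8L)
})

test_that("generation is deterministic in params + seed and truth is
           consistent with the dataset", {
  params <- simulation_params(n_genes = 80, periods = 2,
                              donors_per_period = 3, regions = c("DFC", "MD"))
  a <- simulate_study(params, 11)
  b <- simulate_study(params, 11)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)
  expect_identical(a$loci, b$loci)
  c_ <- simulate_study(params, 12)
  expect_false(identical(a$dataset$values, c_$dataset$values))

  expect_true(all(a$truth$variability_genes %in% a$dataset$genes$gene_id))
  expect_true(all(a$truth$risk_genes %in% a$dataset$genes$gene_id))
  expect_length(intersect(a$truth$variability_genes, a$truth$risk_genes), 0)
  # planted sets avoid sex chromosomes and the exclusion window
  ann <- a$annotation
  planted <- c(a$truth$variability_genes, a$truth$risk_genes)
  expect_true(all(ann$chromosome[match(planted, ann$gene_id)] %in%
                    as.character(1:22)))
})

test_that("male/female SD ratio of inflated genes matches lambda", {
  params <- simulation_params(n_genes = 400, periods = 2,
                              donors_per_period = 50, regions = "DFC",
                              lambda = 2, rho_star = 0, replicate_prob = 0,
                              n_outliers = 0)
  sim <- simulate_study(params, 31)
  v <- log2(sim$dataset$values)
  male <- sim$dataset$samples$sex == "M"
  sd_m <- apply(v[, male], 1, sd)
  sd_f <- apply(v[, !male], 1, sd)
  inflated <- rownames(v) %in% sim$truth$variability_genes
  ratio_inf <- mean(sd_m[inflated] / sd_f[inflated])
  expect_lt(abs(ratio_inf - 2) / 2, 0.15)
  ratio_bg <- mean(sd_m[!inflated] / sd_f[!inflated])
  expect_lt(abs(ratio_bg - 1), 0.1)
})

test_that("the latent factor yields the target cross-correlation in males", {
  params <- simulation_params(n_genes = 400, periods = 2,
                              donors_per_period = 50, regions = "DFC",
                              lambda = 2, rho_star = 0.3,
                              replicate_prob = 0)
  sim <- simulate_study(params, 37)
  v <- log2(sim$dataset$values)
  male_ids <- sim$dataset$samples$sample_id[sim$dataset$samples$sex == "M"]
  rho <- median_cross_correlation(
    list(values = v, genes = sim$dataset$genes),
    sim$truth$variability_genes, sim$truth$risk_genes,
    sample_ids = male_ids)
  expect_lt(abs(rho - 0.3), 0.1)

  params0 <- simulation_params(n_genes = 400, periods = 2,
                               donors_per_period = 50, regions = "DFC",
                               lambda = 1, rho_star = 0,
                               replicate_prob = 0)
  sim0 <- simulate_study(params0, 38)
  v0 <- log2(sim0$dataset$values)
  rho0 <- median_cross_correlation(
    list(values = v0, genes = sim0$dataset$genes),
    sim0$truth$variability_genes, sim0$truth$risk_genes,
    sample_ids = sim0$dataset$samples$sample_id[
      sim0$dataset$samples$sex == "M"])
  expect_lt(abs(rho0), 0.1)
})

test_that("with lambda 1 and no factor, sex SD differences are only noise", {
  params <- simulation_params(n_genes = 300, periods = 2,
                              donors_per_period = 30, regions = "DFC",
                              lambda = 1, rho_star = 0, replicate_prob = 0)
  sim <- simulate_study(params, 41)
  v <- log2(sim$dataset$values)
  male <- sim$dataset$samples$sex == "M"
  lr <- log(apply(v[, male], 1, sd) / apply(v[, !male], 1, sd))
  # two-sided z-test per gene at alpha = 0.05 rejects at the nominal rate
  z <- lr / sqrt(1 / (2 * (sum(male) - 1)) + 1 / (2 * (sum(!male) - 1)))
  rate <- mean(abs(z) > qnorm(0.975))
  expect_lt(rate, 0.12)
})

test_that("synthetic loci recover the planted risk set exactly and exercise
           the exclusion window and density matching", {
  params <- simulation_params(n_genes = 300, n_risk_genes = 12)
  gen <- generate_annotation(params, seed = 6)
  cfg <- analysis_config(mhc_region = gen$mhc_region)
  rs <- suppressMessages(select_risk_genes(gen$loci, gen$annotation, cfg))
  expect_setequal(rs$gene_id, gen$risk_genes)
  # the decoy locus sits inside the exclusion window: none of its genes
  # appear in the recovered set
  expect_length(intersect(rs$gene_id, gen$mhc_genes), 0)
  # uniform density track lets density matching find windows quickly
  set.seed(9)
  dm <- suppressMessages(density_matched_loci_geneset(
    gen$loci[1:3], gen$density, gen$annotation, cfg))
  expect_gte(nrow(dm), 1L)

  # injected outliers are flagged by the outlier rule; per-sex sample
  # counts must exceed ~9 or a single outlier cannot reach 3 SD at all
  # (the extreme-score bound (n-1)/sqrt(n) caps the attainable deviation)
  params_o <- simulation_params(n_genes = 150, periods = 2,
                                donors_per_period = 8,
                                regions = c("DFC", "MFC"),
                                replicate_prob = 0, n_outliers = 1,
                                outlier_magnitude = 10, frac_x_genes = 0)
  sim_o <- simulate_study(params_o, 13)
  ds <- log2_transform(sim_o$dataset, offset = 0)
  model <- covariate_model(impute_ph(ds)$samples,
                           terms = c("age_days", "rin"))
  res <- residualize(impute_ph(ds), model)
  out <- detect_outliers(res)
  expect_true(sim_o$truth$outlier_samples %in% out$flagged)
})
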
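toy_annotation <- function() {
  data.frame(
    gene_id = c("A", "B", "C", "D", "E", "M1"),
    chromosome = c("2", "2", "2", "3", "3", "6"),
    start = c(1100, 2000, 5000, 100, 9000, 25e6 + 10),
    end = c(1500, 3000, 6000, 300, 9500, 25e6 + 500),
    stringsAsFactors = FALSE)
}

toy_locus <- function(id, chrom, start, end, positions, ps) {
  list(locus_id = id, chromosome = chrom, start = start, end = end,
       variants = data.frame(position = positions, p_value = ps))
}

test_that("closest-gene selection follows containment, the most significant
           variant, MHC exclusion, and dedup across loci", {
  ann <- toy_annotation()
  cfg <- analysis_config()
  # variant at 1000: A spans 1100-1500 (distance 100), B at 2000 (500)
  l1 <- toy_locus("L1", "2", 900, 3200, 1000, 1e-10)
  # two variants; the more significant (1e-12 at 5500) sits inside C
  l2 <- toy_locus("L2", "2", 1000, 6500, c(1300, 5500), c(1e-8, 1e-12))
  rs <- suppressMessages(select_risk_genes(list(l1, l2), ann, cfg))
  expect_identical(rs$gene_id, c("A", "C"))

  # containment beats proximity
  l3 <- toy_locus("L3", "2", 900, 3200, 1400, 1e-9)   # inside A
  rs3 <- select_risk_genes(list(l3), ann, cfg)
  expect_identical(rs3$gene_id, "A")

  # duplicated closest gene across two loci collapses to one entry
  l4 <- toy_locus("L4", "2", 1000, 1600, 1200, 1e-9)
  expect_message(rs4 <- select_risk_genes(list(l3, l4), ann, cfg),
                 "collapsed")
  expect_identical(rs4$gene_id, "A")

  # a locus whose only gene lies in the MHC region is skipped
  lm <- toy_locus("LM", "6", 25e6, 25e6 + 1000, 25e6 + 100, 1e-9)
  expect_message(expect_error(select_risk_genes(list(lm), ann, cfg),
                              "no risk genes"), "skipped")
  rs5 <- suppressMessages(select_risk_genes(list(l1, lm), ann, cfg))
  expect_identical(rs5$gene_id, "A")
})

test_that("median cross-correlation matches hand computation, is symmetric,
           and excludes self pairs", {
  set.seed(3)
  values <- matrix(rnorm(6 * 4), 6, 4,
                   dimnames = list(c("g1", "g2", "g3", "g4", "g5", "g6"),
                                   sprintf("s%d", 1:4)))
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:4), donor_id = sprintf("d%d", 1:4),
    sex = "M", age_days = 500, region = "DFC", rin = 9, pmi_hours = 1,
    ph = 6.5, batch = "b1")
  ds <- expression_dataset(values, data.frame(gene_id = rownames(values)),
                           samples, scale = "residual")
  got <- median_cross_correlation(ds, "g1", c("g2", "g3"))
  expect_equal(got, median(c(oracle_pearson(values["g1", ], values["g2", ]),
                             oracle_pearson(values["g1", ], values["g3", ]))))
  expect_equal(median_cross_correlation(ds, c("g2", "g3"), "g1"), got)
  expect_equal(
    median_cross_correlation(ds, c("g1", "g2", "g3"), c("g4", "g5")),
    median_cross_correlation(ds, c("g3", "g1", "g2"), c("g5", "g4")))

  expect_error(median_cross_correlation(ds, "g1", "g1"), "no valid pairs")
  # identical values under distinct ids give correlation 1
  copy <- ds
  copy$values <- rbind(values, values["g1", , drop = FALSE])
  copy$genes <- data.frame(gene_id = c(rownames(values), "g1copy"))
  rownames(copy$values) <- copy$genes$gene_id
  expect_equal(median_cross_correlation(copy, "g1", "g1copy"), 1.0)
  expect_error(median_cross_correlation(ds, "absent", "g2"),
               "empty gene-set")
})

test_that("random-per-locus selection is uniform and respects MHC/dedup", {
  ann <- toy_annotation()
  cfg <- analysis_config()
  l_two <- toy_locus("L", "2", 900, 3200, 1000, 1e-9)  # genes A and B
  set.seed(13)
  draws <- replicate(600, random_gene_per_locus(list(l_two), ann,
                                                cfg)$gene_id)
  tab <- table(factor(draws, levels = c("A", "B")))
  expect_gt(chisq.test(tab)$p.value, 0.001)

  l_single <- toy_locus("S", "3", 50, 400, 200, 1e-9)
  expect_identical(random_gene_per_locus(list(l_single), ann, cfg)$gene_id,
                   "D")
  lm <- toy_locus("LM", "6", 25e6, 25e6 + 1000, 25e6 + 100, 1e-9)
  expect_message(expect_error(random_gene_per_locus(list(lm), ann, cfg)),
                 "skipped")
})

test_that("same-chromosome sets pick distinct genes uniformly", {
  ann <- toy_annotation()
  cfg <- analysis_config()
  ref <- structure(data.frame(gene_id = "D", stringsAsFactors = FALSE),
                   label = "ref")
  # chromosome 3 has exactly two genes: the other one must be chosen
  expect_identical(same_chromosome_geneset(ref, ann, cfg,
                                           seed = 1)$gene_id, "E")
  ref2 <- data.frame(gene_id = c("A", "B"))
  set.seed(2)
  for (i in 1:25) {
    gs <- same_chromosome_geneset(ref2, ann, cfg)
    expect_equal(nrow(gs), 2L)
    expect_false(anyDuplicated(gs$gene_id) > 0)
    expect_true(all(gs$gene_id %in% c("A", "B", "C")))
    expect_false(gs$gene_id[1] == "A")
    expect_false(gs$gene_id[2] == "B")
  }
})

test_that("density-matched windows respect the tolerance and find genes", {
  ann <- toy_annotation()
  cfg <- analysis_config()
  density <- data.frame(chromosome = "2",
                        start = seq(1, 20001, by = 5000),
                        end = seq(5000, 25000, by = 5000), count = 10)
  loci <- list(toy_locus("L1", "2", 1000, 3000, 1500, 1e-9))
  set.seed(4)
  gs <- density_matched_loci_geneset(loci, density, ann, cfg)
  expect_equal(nrow(gs), 1L)
  expect_true(gs$gene_id %in% c("A", "B", "C"))
  # a chromosome without density track is skipped
  loci2 <- list(toy_locus("L2", "3", 100, 300, 200, 1e-9))
  expect_message(expect_error(
    density_matched_loci_geneset(loci2, density, ann, cfg)),
    "no density track")
})

test_that("external gene lists are annotated, deduplicated, and autosomal", {
  ann <- toy_annotation()
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A", "B", "B", "M1", "nope"), path)
  expect_message(gs <- external_geneset(path, ann), "unknown gene id")
  # duplicates collapse, unknown ids drop; M1 is autosomal (chromosome 6)
  # and external sets apply no MHC rule, so it stays
  expect_identical(gs$gene_id, c("A", "B", "M1"))
  expect_true(attr(gs, "label") == sub("\\.txt$", "", basename(path)))
  writeLines("unknown_only", path)
  expect_error(suppressMessages(external_geneset(path, ann)), "no annotated")
})

test_that("co-expression test finds a planted shared factor and its FWER
           arithmetic", {
  params <- simulation_params(
    n_genes = 600, periods = 2, donors_per_period = 8,
    regions = c("DFC", "MFC", "VFC"), lambda = 2, rho_star = 0.4,
    n_risk_genes = 20, replicate_prob = 0, frac_x_genes = 0.04)
  sim <- simulate_study(params, 19)
  cfg <- analysis_config(n_point_resamples = 20, n_null_resamples = 80,
                         n_null_inner_coexpr = 3, top_k = 25,
                         surrogate_count = 0)
  pp <- preprocess_pipeline(sim$dataset, cfg, "microarray")
  strata <- build_strata(pp$dataset, cfg = cfg)
  st <- Filter(function(s) s$cluster_id == 2 && !s$excluded, strata)[[1]]
  sds <- resampled_gene_sd_pair(st, pp$dataset, cfg, seed = 2)
  vg <- select_variability_genes(sds$male, sds$female, cfg)
  rs <- select_risk_genes(sim$loci, sim$annotation,
                          analysis_config(mhc_region = sim$mhc_region))
  suppressMessages(
    cx <- coexpression_test(st, pp$dataset, vg, rs, sds$male, cfg, seed = 6))
  expect_gt(cx$rho, cx$null_mean)
  expect_lt(cx$empirical_p, 0.2)
  expect_equal(cx$corrected_p, min(1, cx$empirical_p * 22))
  expect_equal(cx$n_risk_genes, nrow(rs))

  # an exact copy of a gene under a new id correlates perfectly
  g1 <- vg$gene_id[1]
  dup_ds <- pp$dataset
  copy <- pp$dataset$values[g1, , drop = FALSE]
  rownames(copy) <- paste0(g1, "_copy")
  dup_ds$values <- rbind(dup_ds$values, copy)
  dup_ds$genes <- data.frame(gene_id = rownames(dup_ds$values))
  male_ids <- st$sample_ids[
    pp$dataset$samples$sex[match(st$sample_ids,
                                 pp$dataset$samples$sample_id)] == "M"]
  expect_equal(median_cross_correlation(dup_ds, g1, paste0(g1, "_copy"),
                                        sample_ids = male_ids), 1.0)
})

test_that("age-window scan slides a 4-age window and localizes effects", {
  # 6 distinct donor ages -> exactly 3 windows
  params <- simulation_params(n_genes = 60, periods = 10,
                              donors_per_period = 3,
                              regions = c("DFC", "MFC"),
                              replicate_prob = 0, frac_x_genes = 0,
                              n_risk_genes = 5, rho_star = 0)
  sim <- simulate_study(params, 23)
  ds <- log2_transform(sim$dataset, offset = 0)
  cfg <- analysis_config(n_point_resamples = 5)
  out <- suppressWarnings(age_window_scan(
    ds, 2, bins = 8:10, sim$truth$variability_genes[1:10],
    sim$truth$risk_genes, cfg, seed = 2))
  expect_equal(nrow(out), 3L)
  expect_true(all(diff(out$mean_age_days) > 0))

  one_age <- ds
  one_age$samples$age_days <- 3000
  expect_error(age_window_scan(one_age, 2, bins = 8:10,
                               sim$truth$variability_genes[1:10],
                               sim$truth$risk_genes, cfg, seed = 2),
               "distinct donor ages")
})

test_that("closest-gene risk sets outcoexpress same-chromosome random sets
           when only they share the factor", {
  wins <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    sim <- small_study(seed = 300 + s, rho = 0.4)
    cfg <- analysis_config(n_point_resamples = 15, top_k = 25,
                           surrogate_count = 0,
                           mhc_region = sim$mhc_region)
    pp <- preprocess_pipeline(sim$dataset, cfg, "microarray")
    strata <- build_strata(pp$dataset, cfg = cfg)
    st <- Filter(function(s) s$cluster_id == 2 && !s$excluded, strata)[[1]]
    sds <- resampled_gene_sd_pair(st, pp$dataset, cfg, seed = s)
    vg <- select_variability_genes(sds$male, sds$female, cfg)
    rs <- suppressMessages(select_risk_genes(sim$loci, sim$annotation, cfg))
    rand <- same_chromosome_geneset(rs, sim$annotation, cfg, seed = s)
    score <- function(genes) {
      set.seed(derive_seed(s, "score"))
      mean(replicate(15, {
        d <- draw_male_resample(st, cfg)
        median_cross_correlation(pp$dataset, vg$gene_id, genes,
                                 sample_ids = d$male_samples)
      }))
    }
    if (score(rs$gene_id) > score(rand$gene_id)) wins <- wins + 1L
  }
  expect_gte(wins, n_seeds - 1L)
})
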
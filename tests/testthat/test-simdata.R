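test_that("config validation names the offending field", {
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(n_truncal_snvs = -1), "n_truncal_snvs")
  expect_error(sim_config(purity_per_sample = 1.2), "purity_per_sample")
  expect_error(sim_config(ploidy = 0), "ploidy")
  expect_error(cgr_spec("chr1", n_svs = 3), "n_svs")
  expect_error(cgr_spec("chr1", style = "multichromosomal"), "chromosomes")
  expect_error(cgr_spec(c("chr1", "chr2"), n_svs = 6,
                        style = "multichromosomal"), "n_svs")
  expect_error(sim_config(cgr_specs = list(
    cgr_spec("chr1"), cgr_spec("chr1"))), "disjoint")
  expect_error(sim_config(cgr_specs = list(cgr_spec("chrZ"))), "genome")
})

test_that("an all-zero config yields a cohort with no somatic variants", {
  cfg <- sim_config(n_samples = 1, n_truncal_snvs = 0, n_shared_snvs = 0,
                    n_private_snvs = 0, n_background_svs = 0, seed = 1)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$samples$S1$svs), 0)
  expect_equal(nrow(cohort$samples$S1$snvs), 0)
  expect_equal(nrow(cohort$truth$snvs), 0)
  expect_equal(nrow(cohort$truth$svs), 0)
})

test_that("identical seeds give byte-identical cohort files", {
  cfg <- acceptance_cohort_config(seed = 7)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth-tree bookkeeping matches the configured counts", {
  cfg <- sim_config(n_samples = 4, n_truncal_snvs = 50, n_shared_snvs = 0,
                    n_private_snvs = 10, n_background_svs = 0, seed = 3)
  cohort <- simulate_cohort(cfg)
  tab <- table(cohort$truth$snvs$clonality)
  expect_equal(unname(tab["truncal"]), 50L)
  expect_equal(unname(tab["private"]), 40L) # 10 per leaf branch
  expect_false("shared" %in% names(tab))
  per_branch <- table(cohort$truth$snvs$branch_id)
  leaf_branches <- vapply(cohort$truth$branches, function(b) {
    if (b$type == "private") b$branch_id else NA_character_
  }, "")
  expect_true(all(per_branch[stats::na.omit(leaf_branches)] == 10))
})

test_that("every emitted somatic variant maps to exactly one truth branch", {
  cohort <- simulate_cohort(acceptance_cohort_config(seed = 15))
  expect_false(anyDuplicated(cohort$truth$snvs$key) > 0)
  expect_false(anyDuplicated(cohort$truth$svs$id) > 0)
  for (s in names(cohort$samples)) {
    expect_true(all(cohort$samples[[s]]$snvs$key %in% cohort$truth$snvs$key))
    expect_true(all(cohort$samples[[s]]$svs$id %in% cohort$truth$svs$id))
  }
})

test_that("planted chromothripsis is one interleaving component with oscillating copy number", {
  set.seed(21)
  res <- plant_cgr(cgr_spec("chr2", n_svs = 6), default_genome())
  expect_equal(nrow(res$svs), 6)
  comps <- oracle_components(res$svs)
  expect_equal(length(comps), 1)
  expect_equal(length(comps[[1]]), 6)
  # oscillation between exactly two copy-number states over the footprint
  cn <- res$cn_pieces$copy_number
  expect_equal(sort(unique(cn)), c(2, 3))
  expect_true(all(diff(cn) != 0))
})

test_that("multichromosomal planting reaches the gene target copies", {
  set.seed(22)
  res <- plant_cgr(cgr_spec(c("chr15", "chr9"), n_svs = 8,
                            style = "multichromosomal",
                            amplified_gene = "Myc", target_copies = 8),
                   default_genome())
  tra <- res$svs[res$svs$svtype == "TRA", ]
  expect_gte(nrow(tra), 1)
  segs <- res$cn_pieces
  segs$log2_fold_change <- NA
  expect_equal(gene_weighted_cn("Myc", default_gene_models(), segs), 8)
  expect_error(plant_cgr(cgr_spec("chrNope"), default_genome()),
               "not in genome")
})

test_that("simulated depth tables follow the biallelic-deletion expectation", {
  set.seed(9)
  d1 <- emit_depth_table(purity = 1, depth_mean = 100, sample_ids = "t")
  expect_lt(d1$mean_depth[d1$region == "edit"], 1) # fully deleted
  d0 <- emit_depth_table(purity = 0, depth_mean = 100, sample_ids = "n")
  expect_equal(d0$mean_depth[d0$region == "edit"],
               d0$mean_depth[d0$region == "flank"], tolerance = 0.05)
  d6 <- emit_depth_table(purity = 0.6, depth_mean = 100, sample_ids = "t")
  expect_equal(d6$mean_depth[d6$region == "edit"], 40, tolerance = 0.05)
})

test_that("breakpoint jitter and dropout knobs perturb the emitted calls", {
  cfg0 <- sim_config(n_samples = 2, n_truncal_snvs = 10, n_shared_snvs = 0,
                     n_private_snvs = 0, n_background_svs = 10, seed = 4)
  clean <- simulate_cohort(cfg0)
  cfgj <- sim_config(n_samples = 2, n_truncal_snvs = 10, n_shared_snvs = 0,
                     n_private_snvs = 0, n_background_svs = 10,
                     breakpoint_jitter = 5, seed = 4)
  jittered <- simulate_cohort(cfgj)
  expect_false(all(clean$samples$S1$svs$pos1 == jittered$samples$S1$svs$pos1))
  cfgd <- sim_config(n_samples = 2, n_truncal_snvs = 200, n_shared_snvs = 0,
                     n_private_snvs = 0, n_background_svs = 0,
                     dropout_rate = 0.3, seed = 4)
  dropped <- simulate_cohort(cfgd)
  expect_lt(nrow(dropped$samples$S1$snvs), 200)
})
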
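models3 <- local({
  g <- data.frame(gene = "GeneA", chrom = "chr1", strand = "+",
                  start = 1000, end = 11000, stringsAsFactors = FALSE)
  e <- data.frame(gene = "GeneA", chrom = "chr1",
                  start = c(1000, 5000, 10000), end = c(1200, 5400, 11000),
                  stringsAsFactors = FALSE)
  structure(list(genes = g, exons = e), class = "gene_models")
})

test_that("gene copy number is a length-weighted mean over the gene body", {
  segs <- mk_seg("chr1", 0, 2e4, cn = 5)
  expect_equal(gene_weighted_cn("GeneA", models3, segs), 5.0)
  # 40% of the gene at CN 6, 60% at CN 4 -> 4.8
  segs2 <- rbind(mk_seg("chr1", 0, 5000, cn = 6),     # 4000/10000 of body
                 mk_seg("chr1", 5000, 2e4, cn = 4))
  expect_equal(gene_weighted_cn("GeneA", models3, segs2), 4.8)
  expect_warning(cn <- gene_weighted_cn("GeneA", models3,
                                        mk_seg("chr2", 0, 1e4, cn = 2)),
                 "coverage")
  expect_true(is.na(cn))
  expect_error(gene_weighted_cn("Nope", models3, segs), "not in models")
})

test_that("copy-number calls respect amplification and focality boundaries", {
  amp <- call_gene_cn("GeneA", 5.0, 2.0)
  expect_equal(amp$category, "amplification")
  expect_null(call_gene_cn("GeneA", 4.999, 2.0))
  del <- call_gene_cn("GeneA", 0.4, 2.0)
  expect_equal(del$category, "focal_deletion")
  expect_null(call_gene_cn("GeneA", 0.4, 0.8))   # difference 0.4 < 0.5
  expect_equal(call_gene_cn("GeneA", 0.5, 1.0)$category, "focal_deletion")
  expect_null(call_gene_cn("GeneA", 0.5001, 1.5))
  expect_null(call_gene_cn("GeneA", NA, 2.0))
})

test_that("SV disruption needs an exonic breakpoint, or gene body for translocations", {
  exonic <- mk_sv("chr1", 5100, 9000, "DEL")      # pos1 in exon 2
  intronic <- mk_sv("chr1", 2000, 4000, "DUP")    # both breakpoints intronic
  tra_intron <- mk_sv("chr1", 3000, 5e6, "TRA", chrom2 = "chr9")
  tra_outside <- mk_sv("chr1", 5e5, 5e6, "TRA", chrom2 = "chr9")
  expect_equal(nrow(call_sv_disruption("GeneA", models3, exonic)), 1)
  expect_equal(nrow(call_sv_disruption("GeneA", models3, intronic)), 0)
  expect_equal(nrow(call_sv_disruption("GeneA", models3, tra_intron)), 1)
  expect_equal(nrow(call_sv_disruption("GeneA", models3, tra_outside)), 0)
})

test_that("small-variant calls apply the impact-and-consequence filter", {
  variants <- mk_snvs(c(100, 200, 300, 400))
  ann <- data.frame(
    key = variants$key,
    gene = "GeneA",
    consequence = c("stop_gained", "synonymous_variant", "missense_variant",
                    "missense_variant"),
    impact = c("HIGH", "LOW", "MODERATE", "MODERATE"),
    deleterious = c(NA, NA, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  res <- call_small_variants(variants, ann)
  expect_equal(nrow(res$calls), 2) # stop_gained + deleterious missense
  expect_setequal(res$calls$evidence, variants$key[c(1, 3)])
  res2 <- call_small_variants(mk_snvs(99999), ann)
  expect_equal(nrow(res2$calls), 0)
  expect_equal(res2$n_unannotated, 1)
})

test_that("CGR co-occurrence flags distinguish same-chromosome from direct overlap", {
  myc_models <- default_gene_models()
  amp <- alteration_row <- call_gene_cn("Myc", 8, 2, sample_id = "S1")
  overlapping <- list(clusters = data.frame(
    cluster_id = "c1", chrom = "chr15", start = 61800000, end = 62100000,
    n_svs = 5L, stringsAsFactors = FALSE))
  same_chr <- list(clusters = data.frame(
    cluster_id = "c1", chrom = "chr15", start = 1e6, end = 2e6,
    n_svs = 5L, stringsAsFactors = FALSE))
  other_chr <- list(clusters = data.frame(
    cluster_id = "c1", chrom = "chr10", start = 1e6, end = 2e6,
    n_svs = 5L, stringsAsFactors = FALSE))
  f1 <- flag_cgr_cooccurrence(amp, myc_models, overlapping)
  expect_true(f1$cgr_same_chromosome && f1$cgr_direct_overlap)
  f2 <- flag_cgr_cooccurrence(amp, myc_models, same_chr)
  expect_true(f2$cgr_same_chromosome)
  expect_false(f2$cgr_direct_overlap)
  f3 <- flag_cgr_cooccurrence(amp, myc_models, other_chr)
  expect_false(f3$cgr_same_chromosome || f3$cgr_direct_overlap)
})

test_that("alteration matrix deduplicates mice and excludes engineered cases", {
  mice <- sprintf("m%02d", 1:22)
  samples <- data.frame(sample_id = paste0(mice, "_p"), mouse_id = mice,
                        is_primary = TRUE, stringsAsFactors = FALSE)
  # mouse m01 has 9 extra regions, all altered: must count once
  extra <- data.frame(sample_id = sprintf("m01_r%d", 1:9), mouse_id = "m01",
                      is_primary = FALSE, stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(c(paste0(mice[1:12], "_p"),
                                   sprintf("m01_r%d", 1:9)), function(s) {
    call_gene_cn("Pten", 0.2, 2.0, sample_id = s)
  }))
  res <- build_alteration_matrix(calls, rbind(samples, extra),
                                 gene_panel = c("Pten", "Myc"))
  expect_equal(res$frequency$n_altered[res$frequency$gene == "Pten"], 12)
  expect_equal(res$frequency$frequency[res$frequency$gene == "Pten"],
               12 / 22)
  expect_equal(res$frequency$frequency[res$frequency$gene == "Myc"], 0)
  # engineered mice drop out of the denominator of their gene
  res2 <- build_alteration_matrix(calls, rbind(samples, extra), c("Pten"),
                                  engineered = list(Pten = c("m21", "m22")))
  expect_equal(res2$frequency$n_eligible, 20)
  # order invariance
  shuffled <- calls[rev(seq_len(nrow(calls))), ]
  res3 <- build_alteration_matrix(shuffled, rbind(samples, extra),
                                  gene_panel = c("Pten", "Myc"))
  expect_equal(res3$frequency, res$frequency)
})

test_that("category priority fills matrix cells: amplification beats small_variant", {
  samples <- data.frame(sample_id = "s1", mouse_id = "m1", is_primary = TRUE,
                        stringsAsFactors = FALSE)
  low <- call_small_variants(
    mk_snvs(100, sample_id = "s1"),
    data.frame(key = mk_snvs(100)$key, gene = "G", impact = "HIGH",
               consequence = "stop_gained", deleterious = NA,
               stringsAsFactors = FALSE),
    sample_id = "s1")$calls
  high <- call_gene_cn("G", 8, 2, sample_id = "s1")
  res <- build_alteration_matrix(rbind(low, high), samples, "G")
  expect_equal(unname(res$matrix["G", "m1"]), "amplification")
})

test_that("gene calls on the synthetic cohort reproduce the planted truth", {
  cfg <- acceptance_cohort_config(seed = 13)
  cohort <- simulate_cohort(cfg)
  models <- cfg$genes
  for (s in names(cohort$samples)) {
    seg <- cohort$samples[[s]]$segments
    calls <- list()
    for (g in models$genes$gene) {
      gcn <- suppressWarnings(gene_weighted_cn(g, models, seg))
      ccn <- chromosome_average_cn(models$genes$chrom[models$genes$gene == g],
                                   seg)
      calls[[g]] <- call_gene_cn(g, gcn, ccn, sample_id = s)
    }
    calls <- do.call(rbind, calls)
    amp <- calls[calls$category == "amplification", ]
    expect_setequal(amp$gene, cohort$truth$genes$gene)
  }
})
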
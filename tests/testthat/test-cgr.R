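test_that("interleaving means partial overlap without containment", {
  a <- mk_sv("chr1", 0, 100)
  expect_true(interleaved(a, mk_sv("chr1", 50, 150)))
  expect_false(interleaved(a, mk_sv("chr1", 10, 90)))   # nested
  expect_false(interleaved(a, mk_sv("chr1", 200, 300))) # disjoint
  expect_false(interleaved(a, mk_sv("chr1", 100, 200))) # touching
  expect_false(interleaved(a, mk_sv("chr2", 50, 150)))  # other chromosome
  expect_false(interleaved(a, a))                        # self-containment
})

test_that("clusters are interleaving components with >= 4 members", {
  chain4 <- mk_svs(p1 = c(0, 50, 100, 150), p2 = c(100, 150, 200, 250))
  res <- detect_clusters(chain4)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_svs, 4)
  expect_equal(res$clusters$start, 0)
  expect_equal(res$clusters$end, 250)
  expect_setequal(res$members$sv_id, chain4$id)
  chain3 <- mk_svs(p1 = c(0, 50, 100), p2 = c(100, 150, 200))
  expect_equal(nrow(detect_clusters(chain3)$clusters), 0)
  two <- rbind(mk_svs(p1 = c(0, 50, 100, 150), p2 = c(100, 150, 200, 250)),
               mk_svs(p1 = 1e6 + c(0, 50, 100, 150, 200),
                      p2 = 1e6 + c(100, 150, 200, 250, 300), chrom = "chr2"))
  res2 <- detect_clusters(two)
  expect_equal(sort(res2$clusters$n_svs), c(4L, 5L))
})

test_that("detect_clusters matches the brute-force interleaving oracle on random instances", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    p1 <- sample.int(5e3, n)
    len <- sample.int(2e3, n)
    svs <- mk_svs(p1 = p1, p2 = p1 + len,
                  chrom = sample(c("chr1", "chr2"), 1))
    res <- detect_clusters(svs, min_svs = 4)
    got <- sort(vapply(split(res$members$sv_id, res$members$cluster_id),
                       function(x) paste(sort(x), collapse = ","), ""))
    oracle <- oracle_components(svs)
    oracle <- oracle[vapply(oracle, length, 0L) >= 4]
    want <- sort(vapply(oracle, paste, "", collapse = ","))
    expect_equal(unname(got), unname(want))
  }
})

test_that("adding a disjoint SV never changes existing cluster membership", {
  set.seed(12)
  base <- mk_svs(p1 = c(0, 50, 100, 150), p2 = c(100, 150, 200, 250))
  before <- detect_clusters(base)
  extra <- mk_sv("chr1", 1e6, 1.1e6, id = "far_away")
  after <- detect_clusters(rbind(base, extra))
  expect_equal(sort(after$members$sv_id[after$members$cluster_id ==
                                          after$clusters$cluster_id[1]]),
               sort(before$members$sv_id))
})

test_that("direct translocations join clusters across chromosomes", {
  svs <- rbind(
    mk_svs(p1 = c(0, 50, 100, 150) + 1e6, p2 = c(100, 150, 200, 250) + 1e6,
           chrom = "chr7"),
    mk_svs(p1 = c(0, 50, 100, 150) + 2e6, p2 = c(100, 150, 200, 250) + 2e6,
           chrom = "chr15")
  )
  clusters <- detect_clusters(svs)
  tra <- mk_sv("chr7", 1e6 + 120, 2e6 + 120, "TRA", chrom2 = "chr15")
  linked <- link_multichromosomal(clusters, tra)
  expect_equal(length(unique(linked$groups$group_id)), 1)
  expect_true("direct" %in% linked$links$rule)
  # no translocations -> no joins
  unlinked <- link_multichromosomal(clusters, tra[0, ])
  expect_equal(length(unique(unlinked$groups$group_id)), 2)
})

test_that("translocation enrichment joins chromosome pairs at q < 0.01", {
  # counts t_ij = 5, t_i. = 6, t_.j = 6, T = 30 -> p ~ 2.4e-4
  p_single <- fisher_2x2(5, 1, 1, 23, sided = "greater")
  expect_equal(p_single, oracle_fisher(5, 1, 1, 23, "greater"),
               tolerance = 1e-12)
  expect_equal(p_single, 2.44e-4, tolerance = 2e-2)
  # build that tumor: 5 chr7<->chr15 translocations far outside the
  # footprints (no direct rule), 1 chr7<->chr3, 1 chr15<->chr3 and 23
  # background translocations among other chromosomes
  clusters <- detect_clusters(rbind(
    mk_svs(p1 = c(0, 50, 100, 150) + 1e6, p2 = c(100, 150, 200, 250) + 1e6,
           chrom = "chr7"),
    mk_svs(p1 = c(0, 50, 100, 150) + 2e6, p2 = c(100, 150, 200, 250) + 2e6,
           chrom = "chr15")
  ))
  mk_tra <- function(c1, c2, n, offset = 5e7) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      mk_sv(c1, offset + i * 1e4, offset + i * 1e4 + 5, "TRA", chrom2 = c2,
            id = paste0("tra_", c1, "_", c2, "_", i))
    }))
  }
  others <- c("chr2", "chr4", "chr5", "chr6", "chr8", "chr9", "chr10")
  bg <- do.call(rbind, lapply(1:23, function(i) {
    pair <- sample(others, 2)
    mk_sv(pair[1], 1e6 + i * 1e4, 1e6 + i * 1e4, "TRA", chrom2 = pair[2],
          id = paste0("bg_tra", i))
  }))
  set.seed(2)
  tras <- rbind(mk_tra("chr7", "chr15", 5), mk_tra("chr3", "chr7", 1),
                mk_tra("chr3", "chr15", 1), bg)
  linked <- link_multichromosomal(clusters, tras)
  expect_equal(length(unique(linked$groups$group_id)), 1)
  enr <- linked$links[linked$links$chrom_a == "chr15" &
                        linked$links$chrom_b == "chr7", ]
  expect_true(any(enr$rule == "enrichment" & enr$q < 0.01))
})

test_that("breakpoint fraction counts both SV ends against footprints", {
  chain <- mk_svs(p1 = c(0, 50, 100, 150), p2 = c(100, 150, 200, 250))
  clusters <- detect_clusters(chain)
  expect_equal(breakpoint_fraction_in_cgr(chain, clusters), 1.0)
  outside <- mk_sv("chr1", 1e6, 1.1e6, id = "out1")
  expect_equal(breakpoint_fraction_in_cgr(rbind(chain, outside), clusters),
               0.8) # 8 of 10 breakpoints inside
  no_clusters <- detect_clusters(chain[1:2, ])
  expect_equal(breakpoint_fraction_in_cgr(chain, no_clusters), 0)
  expect_true(is.na(breakpoint_fraction_in_cgr(chain[0, ], clusters)))
})

test_that("planted CGRs are recovered with exact membership", {
  cfg <- acceptance_cohort_config(seed = 77)
  cohort <- simulate_cohort(cfg)
  truth <- cohort$truth$clusters
  for (s in names(cohort$samples)) {
    found <- detect_clusters(cohort$samples[[s]]$svs)
    expect_equal(nrow(found$clusters), nrow(truth))
    for (i in seq_len(nrow(truth))) {
      hit <- found$clusters$chrom == truth$chrom[i]
      expect_true(any(hit))
      got <- found$members$sv_id[found$members$cluster_id %in%
                                   found$clusters$cluster_id[hit]]
      expect_setequal(got, strsplit(truth$member_ids[i], ",")[[1]])
    }
  }
})

test_that("planted multichromosomal CGRs carry linking translocations and foldbacks appear in bfb", {
  genome <- default_genome()
  set.seed(4)
  mc <- plant_cgr(cgr_spec(c("chr9", "chr15"), n_svs = 8,
                           style = "multichromosomal"), genome)
  tra <- mc$svs[mc$svs$svtype == "TRA", ]
  expect_gte(nrow(tra), 1)
  expect_setequal(unique(c(tra$chrom1, tra$chrom2)), c("chr9", "chr15"))
  clusters <- detect_clusters(mc$svs)
  linked <- link_multichromosomal(clusters, mc$svs)
  expect_equal(length(unique(linked$groups$group_id)), 1)
  bfb <- plant_cgr(cgr_spec("chr7", n_svs = 5, style = "bfb"), genome)
  expect_true(any(bfb$svs$svtype == "h2hINV"))
  chr7_len <- genome$length[genome$chrom == "chr7"]
  terminal <- bfb$cn_pieces[bfb$cn_pieces$end == chr7_len, ]
  expect_true(nrow(terminal) == 1 && terminal$copy_number < 2)
})
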
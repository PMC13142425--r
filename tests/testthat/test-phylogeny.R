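test_that("presence matrix applies the depth and rescue rules at their boundaries", {
  st <- rbind(
    site_row("m1", "S1", depth = 100, detected = TRUE),
    site_row("m1", "S2", depth = 39),                     # kills the site
    site_row("m2", "S1", depth = 100, detected = TRUE),
    site_row("m2", "S2", depth = 40, hq = 3),             # rescued
    site_row("m3", "S1", depth = 100, detected = TRUE),
    site_row("m3", "S2", depth = 100, hq = 2)             # not rescued
  )
  m <- build_presence_matrix(st)
  expect_equal(rownames(m), c("m2", "m3"))
  expect_equal(unname(m["m2", ]), c(1L, 1L))
  expect_equal(unname(m["m3", ]), c(1L, 0L))
  expect_equal(unname(attr(m, "dropped")["low_depth"]), 1L)
  expect_warning(build_presence_matrix(st[-2, ]), "missing depth")
})

test_that("clonality labels follow the all/subset/one partition", {
  m <- rbind(a = c(1, 1, 1, 1), b = c(1, 0, 0, 0), c = c(1, 1, 0, 0))
  colnames(m) <- paste0("S", 1:4)
  expect_equal(classify_clonality(m),
               c("truncal", "private", "shared"))
  bad <- rbind(z = c(0, 0))
  colnames(bad) <- c("S1", "S2")
  expect_error(classify_clonality(bad), "absent")
})

test_that("Fitch scores match the exhaustive state-assignment oracle", {
  # worked 3-sample example: mutations {all}, {S1}, {S1,S2}
  m <- rbind(mut_all = c(1, 1, 1), mut_s1 = c(1, 0, 0),
             mut_s12 = c(1, 1, 0))
  colnames(m) <- c("S1", "S2", "S3")
  good <- ape::read.tree(text = "((S1,S2),S3);")
  bad <- ape::read.tree(text = "((S1,S3),S2);")
  expect_equal(fitch_score(m, good), 3)
  expect_equal(fitch_score(m, bad), 4)
  # truncal-only matrix scores one change per mutation on any topology
  tr <- matrix(1, nrow = 7, ncol = 3, dimnames = list(NULL, c("S1", "S2", "S3")))
  expect_equal(fitch_score(tr, good), 7)
  expect_equal(fitch_score(tr, bad), 7)
  expect_equal(fitch_score(m[0, , drop = FALSE], good), 0)
  # random matrices vs brute-force minimal-changes oracle
  set.seed(41)
  for (rep in 1:20) {
    n_s <- sample(3:5, 1)
    mm <- matrix(rbinom(n_s * 8, 1, 0.5), ncol = n_s,
                 dimnames = list(NULL, paste0("S", 1:n_s)))
    mm <- mm[rowSums(mm) > 0, , drop = FALSE]
    if (!nrow(mm)) next
    for (tree in oracle_all_topologies(n_s)[1:3]) {
      phy <- ape::read.tree(
        text = cgrscope:::nested_to_newick(tree, paste0("S", 1:n_s)))
      expect_equal(fitch_score(mm, phy), oracle_tree_score(tree, mm))
    }
  }
})

test_that("fitch_score is bounded below by the mutation count", {
  set.seed(55)
  for (rep in 1:10) {
    m <- matrix(rbinom(4 * 12, 1, 0.4), ncol = 4,
                dimnames = list(NULL, paste0("S", 1:4)))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    for (tree in oracle_all_topologies(4)[sample(15, 3)]) {
      phy <- ape::read.tree(
        text = cgrscope:::nested_to_newick(tree, paste0("S", 1:4)))
      expect_gte(fitch_score(m, phy), nrow(m))
    }
  }
})

test_that("exact parsimony search recovers the known optimum", {
  m <- rbind(mut_all = c(1, 1, 1), mut_s1 = c(1, 0, 0),
             mut_s12 = c(1, 1, 0))
  colnames(m) <- c("S1", "S2", "S3")
  fit <- search_parsimony_tree(m)
  expect_equal(fit$score, 3)
  expect_setequal(phylo_clades(fit$tree), c("S1|S2", "S1|S2|S3"))
  # perfect phylogeny from nested presence sets -> zero homoplasy
  pp <- rbind(matrix(rep(c(1, 1, 1, 1), 5), ncol = 4, byrow = TRUE),
              matrix(rep(c(1, 1, 0, 0), 4), ncol = 4, byrow = TRUE),
              matrix(rep(c(1, 0, 0, 0), 3), ncol = 4, byrow = TRUE),
              matrix(rep(c(0, 0, 1, 0), 2), ncol = 4, byrow = TRUE))
  colnames(pp) <- paste0("S", 1:4)
  fit_pp <- search_parsimony_tree(pp)
  expect_equal(fit_pp$score, nrow(pp))
  # weight invariance: duplicating columns x10 keeps the topology
  m10 <- m[rep(seq_len(nrow(m)), 10), ]
  expect_equal(phylo_clades(search_parsimony_tree(m10)$tree),
               phylo_clades(fit$tree))
})

test_that("exact search equals the exhaustive-enumeration oracle on random matrices", {
  set.seed(61)
  for (rep in 1:25) {
    n_s <- sample(4:6, 1)
    m <- matrix(rbinom(n_s * 10, 1, 0.45), ncol = n_s,
                dimnames = list(NULL, paste0("S", 1:n_s)))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) < 2) next
    fit <- search_parsimony_tree(m, mode = "exhaustive")
    expect_equal(fit$score, oracle_min_score(m))
  }
})

test_that("the ratchet reaches the exact optimum on moderate instances", {
  set.seed(71)
  # perfect phylogeny over 10 samples: the ratchet must find score = n_mut
  sets <- list(1:10, 1:5, 6:10, 1:2, 3:5, 6:7, 8:10)
  m <- do.call(rbind, lapply(sets, function(s) {
    row <- rep(0, 10); row[s] <- 1
    matrix(rep(row, 6), ncol = 10, byrow = TRUE)
  }))
  colnames(m) <- paste0("S", 1:10)
  fit <- search_parsimony_tree(m, ratchet_iter = 10)
  expect_equal(fit$method, "ratchet")
  expect_equal(fit$score, nrow(m))
  expect_true(all(c("S1|S2", "S3|S4|S5", "S6|S7", "S10|S8|S9") %in%
                    phylo_clades(fit$tree))) # keys sort lexicographically
})

test_that("branch lengths count clade-exact mutations; homoplasies stay unassigned", {
  m <- rbind(mut_all = c(1, 1, 1), mut_s1 = c(1, 0, 0),
             mut_s12 = c(1, 1, 0), mut_s13 = c(1, 0, 1))
  colnames(m) <- c("S1", "S2", "S3")
  tree <- ape::read.tree(text = "((S1,S2),S3);")
  res <- assign_branch_lengths(tree, m)
  expect_equal(res$tree$root.edge, 1)            # truncal
  expect_equal(unname(res$clade_counts["S1|S2"]), 1L)
  expect_equal(unname(res$clade_counts["S1"]), 1L)
  expect_equal(res$unassigned, 1)                # {S1,S3} is not a clade
  expect_equal(sum(res$tree$edge.length) + res$tree$root.edge +
                 res$unassigned, nrow(m))
  all_truncal <- matrix(1, 5, 3, dimnames = list(NULL, c("S1", "S2", "S3")))
  res2 <- assign_branch_lengths(tree, all_truncal)
  expect_equal(res2$tree$root.edge, 5)
  expect_equal(sum(res2$tree$edge.length), 0)
})

test_that("UPGMA on SV profiles gives the hand-computed ultrametric tree", {
  # profiles: A and B differ in 2 SVs; C differs from both in 4
  mk_set <- function(ids, sample) {
    do.call(rbind, lapply(ids, function(i) {
      mk_sv("chr1", i * 1e5, i * 1e5 + 5e4, id = sprintf("u%02d", i),
            sample_id = sample)
    }))
  }
  sets <- list(A = mk_set(c(1, 2, 3), "A"), B = mk_set(c(1, 2, 4), "B"),
               C = mk_set(c(5, 6, 7), "C"))
  res <- upgma_sv_tree(sets)
  tree <- res$tree
  # d(A,B) = 2 -> join at height 1; C joins at height (4+4+2...)/.. = 3
  dm <- ape::cophenetic.phylo(tree)
  expect_equal(dm["A", "B"], 2)
  expect_equal(dm["A", "C"], 6)
  expect_equal(dm["B", "C"], 6)
  # ultrametric: all tips equidistant from root
  expect_true(ape::is.ultrametric(tree))
  expect_error(upgma_sv_tree(sets["A"]), ">= 2 samples")
})

test_that("UPGMA drops SV groups never exceeding the allele-fraction cutoff", {
  low <- mk_sv("chr1", 1e6, 2e6, id = "low", vaf = 0.1)   # exactly 0.1: out
  high <- mk_sv("chr1", 5e6, 6e6, id = "high", vaf = 0.3)
  sets <- list(A = rbind(low, high), B = rbind(low, high))
  res <- upgma_sv_tree(sets)
  expect_equal(nrow(res$profile), 1)
})

test_that("bootstrap saturates on a strong perfect phylogeny and is seed-stable", {
  pp <- do.call(rbind, lapply(list(c(1, 1, 1, 1), c(1, 1, 0, 0),
                                   c(0, 0, 1, 1)), function(row) {
    matrix(rep(row, 25), ncol = 4, byrow = TRUE)
  }))
  colnames(pp) <- paste0("S", 1:4)
  bs <- bootstrap_support(pp, n_replicates = 30, seed = 9)
  expect_true(all(bs >= 0.95))
  bs2 <- bootstrap_support(pp, n_replicates = 30, seed = 9)
  expect_identical(bs, bs2)
  expect_warning(bootstrap_support(pp[1, , drop = FALSE], n_replicates = 2),
                 "degenerate")
})
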
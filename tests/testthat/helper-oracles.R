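# Shared fixtures and independent oracles. Oracles deliberately use
# different algorithms from the implementation: brute-force pairwise
# checks, full enumeration over tables/topologies/state assignments.

site_row <- function(key, sample, depth = 100, hq = 0, detected = FALSE) {
  data.frame(key = key, sample_id = sample, depth = depth,
             hq_alt_count = hq, detected = detected, stringsAsFactors = FALSE)
}

mk_sv <- function(chrom, p1, p2, type = "DEL", chrom2 = chrom, vaf = 0.35,
                  id = NULL, sample_id = "S1") {
  strands <- list(DEL = c("+", "-"), DUP = c("-", "+"),
                  h2hINV = c("+", "+"), t2tINV = c("-", "-"),
                  TRA = c("+", "-"))[[type]]
  sv_calls(chrom1 = chrom, pos1 = p1, strand1 = strands[1],
           chrom2 = chrom2, pos2 = p2, strand2 = strands[2],
           svtype = type, alt_reads = round(vaf * 100), depth = 100,
           sample_id = sample_id, id = id)
}

mk_svs <- function(p1, p2, chrom = "chr1", type = "DEL") {
  do.call(rbind, lapply(seq_along(p1), function(i) {
    mk_sv(chrom, p1[i], p2[i], type = type, id = sprintf("t%02d", i))
  }))
}

mk_seg <- function(chrom, start, end, cn = NA, log2 = NA) {
  data.frame(chrom = chrom, start = start, end = end,
             log2_fold_change = log2, copy_number = cn,
             stringsAsFactors = FALSE)
}

mk_snvs <- function(pos, chrom = "chr1", ref = "A", alt = "T", vaf = 0.4,
                    depth = 100, sample_id = "S1", callers = "mutect2") {
  snv_calls(chrom = rep_len(chrom, length(pos)), pos = pos,
            ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
            depth = depth, alt_count = round(vaf * depth),
            callers = callers, sample_id = sample_id)
}

# Oracle 1: brute-force interleaving components via all-pairs checks and
# repeated set expansion (no union-find, no sweep).
oracle_components <- function(svs) {
  intra <- svs[svs$chrom1 == svs$chrom2, , drop = FALSE]
  n <- nrow(intra)
  if (!n) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) adj[i, j] <- interleaved(intra[i, ], intra[j, ])
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s
    repeat {
      grow <- which(!seen & Reduce(`|`, lapply(comp, function(i) adj[i, ])))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
      seen[grow] <- TRUE
    }
    seen[comp] <- TRUE
    comps[[length(comps) + 1]] <- sort(intra$id[comp])
  }
  comps
}

# Oracle 2: Fisher exact p by full enumeration over all tables with the
# observed margins, using binomial coefficients directly.
oracle_fisher <- function(a, b, c, d, sided = "two.sided") {
  m <- a + b; n2 <- c + d; k <- a + c
  total <- m + n2
  lo <- max(0, k - n2); hi <- min(k, m)
  prob <- function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(total, k))
  }
  probs <- vapply(lo:hi, prob, 0)
  xs <- lo:hi
  p_obs <- prob(a)
  p <- switch(sided,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[xs >= a]),
    less = sum(probs[xs <= a]))
  min(p, 1)
}

# Oracle 3: exact small-parsimony score of a binary character matrix on a
# nested-list topology by enumerating all internal-node state
# assignments (germline root state fixed at 0).
oracle_tree_score <- function(tree, matrix) {
  samples <- colnames(matrix)
  count_internal <- function(node) {
    if (!is.list(node)) return(0L)
    1L + count_internal(node[[1]]) + count_internal(node[[2]])
  }
  n_int <- count_internal(tree)
  score_char <- function(states) {
    best <- Inf
    for (mask in 0:(2^n_int - 1)) {
      assign_idx <- 0L
      changes <- 0L
      rec <- function(node) {
        if (!is.list(node)) return(states[node])
        assign_idx <<- assign_idx + 1L
        my <- bitwAnd(bitwShiftR(mask, assign_idx - 1L), 1L)
        l <- rec(node[[1]]); r <- rec(node[[2]])
        changes <<- changes + (my != l) + (my != r)
        my
      }
      root_state <- rec(tree)
      total <- changes + (root_state != 0L) # germline outgroup is 0
      if (total < best) best <- total
    }
    best
  }
  sum(apply(matrix != 0, 1, function(row) score_char(as.integer(row))))
}

# All rooted binary topologies over 1..n by sequential insertion (kept
# separate from the package's search code on purpose).
oracle_all_topologies <- function(n) {
  grow <- function(trees, leaf) {
    out <- list()
    insert <- function(node) {
      res <- list(list(node, leaf))
      if (is.list(node)) {
        for (s in insert(node[[1]])) res <- c(res, list(list(s, node[[2]])))
        for (s in insert(node[[2]])) res <- c(res, list(list(node[[1]], s)))
      }
      res
    }
    for (tr in trees) out <- c(out, insert(tr))
    out
  }
  trees <- list(1L)
  if (n >= 2) trees <- list(list(1L, 2L))
  for (leaf in seq_len(n)[-(1:2)]) trees <- grow(trees, leaf)
  trees
}

oracle_min_score <- function(matrix) {
  trees <- oracle_all_topologies(ncol(matrix))
  min(vapply(trees, oracle_tree_score, 0, matrix = matrix))
}

# Clade keys (sorted tip sets of internal nodes) of an ape tree.
phylo_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, rec)))
  }
  internal <- unique(tree$edge[, 1])
  sort(vapply(internal, function(n) paste(rec(n), collapse = "|"), ""))
}

acceptance_cohort_config <- function(seed = 42) {
  sim_config(
    n_samples = 4, n_truncal_snvs = 50, n_shared_snvs = 20,
    n_private_snvs = 10, n_background_svs = 12,
    cgr_specs = list(
      cgr_spec("chr15", n_svs = 6, style = "chromothripsis",
               amplified_gene = "Myc", target_copies = 8),
      cgr_spec("chr7", n_svs = 5, style = "bfb")
    ),
    purity_per_sample = 0.7, depth_mean = 100, seed = seed
  )
}
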
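## Multi-region clonal phylogenetics from binary presence/absence of
## somatic mutations. Trees are rooted by an implicit germline outgroup in
## the all-absent state. Maximum parsimony uses Fitch small parsimony;
## the search is exact (branch and bound over rooted topologies) up to 8
## samples and a parsimony-ratchet heuristic above that. Branch lengths
## are mutation counts: each mutation whose presence set equals a clade of
## the tree increments that clade's branch; presence sets matching no
## clade (homoplasies) are reported as unassigned, never forced onto a
## branch.

#' Build a mutation presence/absence matrix under the multi-region rules
#'
#' A candidate site is retained iff its sequencing depth is at least
#' `min_depth` in every sample. A mutation is present in a sample iff a
#' caller detected it there, or at least `min_hq_alt` high-quality
#' alternate reads (mapping quality >= 30, base quality >= 20) support it
#' (the rescue rule). Sites missing depth data in any sample are dropped
#' with a warning; sites present in no sample after calling are dropped.
#'
#' @param site_table long-format `data.frame` with columns `key`,
#'   `sample_id`, `depth`, `hq_alt_count`, `detected` (logical), one row
#'   per site x sample.
#' @param min_depth minimum depth in every sample (default 40, inclusive).
#' @param min_hq_alt rescue threshold on high-quality alt reads
#'   (default 3, inclusive).
#' @return binary matrix (mutations x samples) with a `clonality`
#'   attribute (see [classify_clonality()]) and a `dropped` attribute
#'   (named counts).
#' @export
build_presence_matrix <- function(site_table, min_depth = 40, min_hq_alt = 3) {
  samples <- sort(unique(site_table$sample_id))
  keys <- unique(site_table$key)
  idx <- matrix(match(
    paste(rep(keys, each = length(samples)), samples),
    paste(site_table$key, site_table$sample_id)
  ), nrow = length(keys), byrow = TRUE)
  incomplete <- rowSums(is.na(idx)) > 0
  if (any(incomplete)) {
    warning(sum(incomplete), " site(s) dropped: missing depth data in >=1 sample")
  }
  idx <- idx[!incomplete, , drop = FALSE]
  keys <- keys[!incomplete]
  depth <- matrix(site_table$depth[idx], nrow = nrow(idx))
  low_depth <- rowSums(depth >= min_depth) < length(samples)
  present <- matrix(site_table$detected[idx] |
                      site_table$hq_alt_count[idx] >= min_hq_alt,
                    nrow = nrow(idx))
  keep <- !low_depth & rowSums(present) > 0
  m <- present[keep, , drop = FALSE] * 1L
  dimnames(m) <- list(keys[keep], samples)
  attr(m, "dropped") <- c(missing_data = sum(incomplete),
                          low_depth = sum(low_depth),
                          absent_everywhere = sum(!low_depth &
                                                    rowSums(present) == 0))
  attr(m, "clonality") <- if (length(samples) >= 2 && nrow(m))
    classify_clonality(m) else NULL
  m
}

#' Classify mutation clonality from a presence matrix
#'
#' Truncal: present in all samples; private: exactly one; shared:
#' otherwise (at least 2, fewer than all).
#'
#' @param matrix binary mutations x samples matrix with >= 2 columns.
#' @return character vector, one label per row.
#' @export
classify_clonality <- function(matrix) {
  if (ncol(matrix) < 2) stop("need >= 2 samples", call. = FALSE)
  n <- rowSums(matrix != 0)
  if (any(n == 0)) {
    stop("mutation(s) absent from every sample: ",
         paste(utils::head(rownames(matrix)[n == 0], 3), collapse = ", "),
         call. = FALSE)
  }
  unname(ifelse(n == ncol(matrix), "truncal",
                ifelse(n == 1, "private", "shared")))
}

## ---- nested-list tree machinery (internal) --------------------------------
## A tree is a leaf (integer sample index) or list(left, right).

# Per-character Fitch changes on a rooted nested tree, with the germline
# outgroup (all-absent) joined above the root. States per char are coded
# 1 = {absent}, 2 = {present}, 3 = both.
fitch_nested <- function(tree, leaf_states) {
  rec <- function(node) {
    if (!is.list(node)) {
      return(list(st = leaf_states[, node], ch = 0L))
    }
    a <- rec(node[[1]])
    b <- rec(node[[2]])
    inter <- bitwAnd(a$st, b$st)
    disjoint <- inter == 0L
    st <- inter
    st[disjoint] <- bitwOr(a$st[disjoint], b$st[disjoint])
    list(st = st, ch = a$ch + b$ch + as.integer(disjoint))
  }
  r <- rec(tree)
  # join with germline {absent}: one more change per char lacking 'absent'
  r$ch + as.integer(bitwAnd(r$st, 1L) == 0L)
}

matrix_to_states <- function(matrix) {
  # chars x samples, coded 1 (absent) / 2 (present)
  states <- (matrix != 0) + 1L
  storage.mode(states) <- "integer"
  states
}

nested_to_newick <- function(tree, labels, canonical = FALSE) {
  rec <- function(node) {
    if (!is.list(node)) return(labels[node])
    parts <- c(rec(node[[1]]), rec(node[[2]]))
    if (canonical) parts <- sort(parts)
    paste0("(", parts[1], ",", parts[2], ")")
  }
  paste0(rec(tree), ";")
}

nested_to_phylo <- function(tree, labels) {
  if (!is.list(tree)) {
    # single-sample degenerate tree
    return(ape::read.tree(text = paste0("(", labels[tree], ");")))
  }
  ape::read.tree(text = nested_to_newick(tree, labels))
}

# All ways to insert `leaf` into rooted tree `node` (above every node,
# including a new root): 2k-1 positions for k leaves.
insert_positions <- function(node, leaf) {
  out <- list(list(node, leaf))
  if (is.list(node)) {
    for (sub in insert_positions(node[[1]], leaf)) {
      out[[length(out) + 1]] <- list(sub, node[[2]])
    }
    for (sub in insert_positions(node[[2]], leaf)) {
      out[[length(out) + 1]] <- list(node[[1]], sub)
    }
  }
  out
}

tree_leaves <- function(node) {
  if (!is.list(node)) return(node)
  c(tree_leaves(node[[1]]), tree_leaves(node[[2]]))
}

# Remove a leaf; collapse the freed internal node.
drop_leaf <- function(node, leaf) {
  if (!is.list(node)) return(if (identical(node, leaf)) NULL else node)
  l <- drop_leaf(node[[1]], leaf)
  r <- drop_leaf(node[[2]], leaf)
  if (is.null(l)) return(r)
  if (is.null(r)) return(l)
  list(l, r)
}

# Exact search: branch and bound over rooted topologies by stepwise leaf
# addition; partial-tree Fitch scores only grow as leaves are added, so a
# partial score > best prunes the subtree of the search. Returns all
# optimal trees.
bnb_search <- function(states, n_leaves, weights = NULL) {
  score_fn <- function(tree) {
    ch <- fitch_nested(tree, states)
    if (is.null(weights)) sum(ch) else sum(ch * weights)
  }
  best <- Inf
  best_trees <- list()
  recurse <- function(tree, next_leaf) {
    s <- score_fn(tree)
    if (s > best) return()
    if (next_leaf > n_leaves) {
      if (s < best) {
        best <<- s
        best_trees <<- list(tree)
      } else {
        best_trees[[length(best_trees) + 1]] <<- tree
      }
      return()
    }
    for (cand in insert_positions(tree, next_leaf)) {
      recurse(cand, next_leaf + 1L)
    }
  }
  if (n_leaves == 1) return(list(score = score_fn(1L), trees = list(1L)))
  recurse(list(1L, 2L), 3L)
  list(score = best, trees = best_trees)
}

# Hill climbing by leaf re-insertion until no move improves the score.
reinsertion_climb <- function(tree, states, weights = NULL, max_pass = 20) {
  score_fn <- function(tr) {
    ch <- fitch_nested(tr, states)
    if (is.null(weights)) sum(ch) else sum(ch * weights)
  }
  cur <- tree
  cur_s <- score_fn(cur)
  leaves <- sort(tree_leaves(tree))
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (lf in leaves) {
      backbone <- drop_leaf(cur, lf)
      if (!is.list(backbone)) next
      for (cand in insert_positions(backbone, lf)) {
        s <- score_fn(cand)
        if (s < cur_s) {
          cur <- cand
          cur_s <- s
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(tree = cur, score = cur_s)
}

#' Fitch parsimony score of a presence matrix on a topology
#'
#' Number of state changes required over all mutations, with a germline
#' outgroup (all-absent) joined above the root. Every mutation needs at
#' least one change, so the score is bounded below by the number of
#' mutations, with equality iff the matrix is a perfect phylogeny on the
#' topology.
#'
#' @param matrix binary mutations x samples matrix (named columns).
#' @param tree `phylo` over exactly the matrix's samples (binary, rooted).
#' @return integer parsimony score.
#' @export
fitch_score <- function(matrix, tree) {
  if (!nrow(matrix)) return(0L)
  if (!setequal(tree$tip.label, colnames(matrix))) {
    stop("tree tips and matrix samples differ", call. = FALSE)
  }
  nested <- phylo_to_nested(tree, colnames(matrix))
  sum(fitch_nested(nested, matrix_to_states(matrix)))
}

phylo_to_nested <- function(tree, sample_order) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    if (node <= ntip) return(match(tree$tip.label[node], sample_order))
    kids <- children[[as.character(node)]]
    subs <- lapply(kids, build)
    out <- subs[[1]]
    for (k in seq_along(subs)[-1]) out <- list(out, subs[[k]])
    out
  }
  build(ntip + 1L)
}

#' Maximum-parsimony topology search
#'
#' Up to `exact_max` samples the search is exact: branch and bound over
#' all rooted topologies, globally optimal, ties broken by the
#' lexicographically smallest canonical newick. Above that, a parsimony
#' ratchet is used: greedy stepwise addition followed by iterations that
#' upweight a random 25% of mutations, hill-climb by leaf re-insertion
#' under the perturbed weights, then re-climb under unit weights. The
#' ratchet consumes the R random number stream; seed with [set.seed()]
#' for reproducibility.
#'
#' @param matrix binary mutations x samples matrix.
#' @param mode `"auto"` (default), `"exhaustive"` or `"ratchet"`.
#' @param exact_max largest sample count handled exhaustively (default 8).
#' @param ratchet_iter ratchet iterations (default 50).
#' @return list with `tree` (`phylo`), `score`, and `method`.
#' @export
search_parsimony_tree <- function(matrix, mode = c("auto", "exhaustive",
                                                   "ratchet"),
                                  exact_max = 8, ratchet_iter = 50) {
  mode <- match.arg(mode)
  samples <- colnames(matrix)
  n <- length(samples)
  if (n < 3) {
    # degenerate: the topology is forced
    tree <- if (n == 1) nested_to_phylo(1L, samples)
            else nested_to_phylo(list(1L, 2L), samples)
    sc <- if (nrow(matrix)) sum(fitch_nested(
      if (n == 1) 1L else list(1L, 2L), matrix_to_states(matrix))) else 0L
    return(list(tree = tree, score = sc, method = "degenerate"))
  }
  states <- matrix_to_states(matrix)
  use_exact <- mode == "exhaustive" || (mode == "auto" && n <= exact_max)
  if (use_exact) {
    res <- bnb_search(states, n)
    nwk <- vapply(res$trees, nested_to_newick, "", labels = samples,
                  canonical = TRUE)
    best <- res$trees[[which(nwk == min(nwk))[1]]]
    return(list(tree = nested_to_phylo(best, samples), score = res$score,
                method = "exhaustive"))
  }
  # parsimony ratchet
  cur <- list(1L, 2L)
  for (lf in 3:n) { # greedy stepwise addition
    cands <- insert_positions(cur, lf)
    sc <- vapply(cands, function(tr) sum(fitch_nested(tr, states)), 0L)
    cur <- cands[[which.min(sc)]]
  }
  climb <- reinsertion_climb(cur, states)
  cur <- climb$tree
  cur_s <- climb$score
  n_char <- nrow(matrix)
  for (it in seq_len(ratchet_iter)) {
    w <- rep(1, n_char)
    up <- sample.int(n_char, size = max(1, round(0.25 * n_char)))
    w[up] <- 2
    pert <- reinsertion_climb(cur, states, weights = w)
    re <- reinsertion_climb(pert$tree, states)
    if (re$score < cur_s) {
      cur <- re$tree
      cur_s <- re$score
    }
  }
  list(tree = nested_to_phylo(cur, samples), score = cur_s,
       method = "ratchet")
}

#' Assign mutation-count branch lengths to a topology
#'
#' Each mutation whose presence set equals the tip set below an edge
#' increments that edge's length; mutations present in all samples count
#' on the root edge (the branch from the germline outgroup to the samples'
#' most recent common ancestor); presence sets matching no clade are
#' counted as unassigned. The branch lengths therefore sum, together with
#' the unassigned count, to the number of mutations.
#'
#' @param tree `phylo` over the matrix's samples.
#' @param matrix binary mutations x samples matrix.
#' @return list with `tree` (`phylo`, `edge.length` = counts, `root.edge`
#'   = truncal count), `unassigned` count, and `clade_counts` (named by
#'   canonical clade string).
#' @export
assign_branch_lengths <- function(tree, matrix) {
  samples <- colnames(matrix)
  if (!setequal(tree$tip.label, samples)) {
    stop("tree tips and matrix samples differ", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  clade_of_node <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, clade_of_node)))
  }
  edge_clades <- lapply(tree$edge[, 2], clade_of_node)
  edge_keys <- vapply(edge_clades, paste, "", collapse = "|")
  counts <- integer(length(edge_keys))
  root_count <- 0L
  unassigned <- 0L
  all_key <- paste(sort(samples), collapse = "|")
  for (i in seq_len(nrow(matrix))) {
    set <- sort(samples[matrix[i, ] != 0])
    key <- paste(set, collapse = "|")
    if (key == all_key) {
      root_count <- root_count + 1L
    } else {
      hit <- match(key, edge_keys)
      if (is.na(hit)) unassigned <- unassigned + 1L
      else counts[hit] <- counts[hit] + 1L
    }
  }
  tree$edge.length <- as.numeric(counts)
  tree$root.edge <- as.numeric(root_count)
  clade_counts <- c(stats::setNames(as.integer(counts), edge_keys),
                    stats::setNames(root_count, all_key))
  list(tree = tree, unassigned = unassigned, clade_counts = clade_counts)
}

#' UPGMA tree from per-sample SV call sets
#'
#' SVs are matched across samples by single-linkage grouping under
#' [sv_equal()]; groups whose allele fraction is strictly greater than
#' `af_min` in at least one sample form the binary SV profile (groups with
#' no allele-fraction information are kept). The tree is average-linkage
#' hierarchical clustering (UPGMA) on Hamming distance between sample
#' profiles; the output is ultrametric.
#'
#' @param sv_sets named list of SV call tables, one per sample.
#' @param af_min strict allele-fraction threshold (default 0.1).
#' @param tol breakpoint tolerance for cross-sample matching.
#' @return list with `tree` (`phylo`), `profile` (groups x samples binary
#'   matrix).
#' @export
upgma_sv_tree <- function(sv_sets, af_min = 0.1, tol = 10) {
  if (length(sv_sets) < 2) stop("need >= 2 samples", call. = FALSE)
  samples <- names(sv_sets)
  pooled <- do.call(rbind, lapply(samples, function(s) {
    x <- sv_sets[[s]]
    if (!nrow(x)) return(NULL)
    x$.sample <- s
    x
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    stop("no SVs in any sample", call. = FALSE)
  }
  grp <- sv_group(pooled, tol = tol)
  prof <- matrix(0L, nrow = max(grp), ncol = length(samples),
                 dimnames = list(NULL, samples))
  max_af <- rep(NA_real_, max(grp))
  for (i in seq_len(nrow(pooled))) {
    prof[grp[i], pooled$.sample[i]] <- 1L
    v <- pooled$vaf[i]
    if (!is.na(v) && (is.na(max_af[grp[i]]) || v > max_af[grp[i]])) {
      max_af[grp[i]] <- v
    }
  }
  keep <- is.na(max_af) | max_af > af_min
  prof <- prof[keep, , drop = FALSE]
  d <- stats::dist(t(prof), method = "manhattan") # Hamming on binary
  hc <- stats::hclust(d, method = "average")
  list(tree = ape::as.phylo(hc), profile = prof)
}

#' Bootstrap support for the clades of a parsimony tree
#'
#' Resamples mutations (matrix rows) with replacement, rebuilds the
#' topology with [search_parsimony_tree()], and reports for each
#' non-trivial clade of the original tree the fraction of replicates
#' containing it.
#'
#' @param matrix binary mutations x samples matrix.
#' @param tree original `phylo`; inferred from `matrix` when `NULL`.
#' @param n_replicates bootstrap replicates (default 100).
#' @param seed RNG seed for reproducibility.
#' @return named numeric vector of support fractions (clades keyed as
#'   `"tipA|tipB|..."`). A single-mutation matrix yields degenerate
#'   support and warns.
#' @export
bootstrap_support <- function(matrix, tree = NULL, n_replicates = 100,
                              seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (nrow(matrix) < 2) {
    warning("bootstrap on <2 mutations is degenerate")
  }
  if (is.null(tree)) {
    tree <- search_parsimony_tree(matrix)$tree
  }
  clades <- tree_clade_keys(tree)
  clades <- clades[vapply(strsplit(clades, "|", fixed = TRUE), length, 0L) >= 2]
  clades <- setdiff(clades, paste(sort(tree$tip.label), collapse = "|"))
  hits <- stats::setNames(numeric(length(clades)), clades)
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(nrow(matrix), replace = TRUE)
    rep_tree <- search_parsimony_tree(matrix[idx, , drop = FALSE])$tree
    rep_clades <- tree_clade_keys(rep_tree)
    hits[clades %in% rep_clades] <- hits[clades %in% rep_clades] + 1
  }
  hits / n_replicates
}

tree_clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, rec)))
  }
  nodes <- unique(tree$edge[, 1])
  vapply(c(seq_len(ntip), nodes), function(n) paste(rec(n), collapse = "|"), "")
}
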
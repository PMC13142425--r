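## Complex genomic rearrangement (CGR) detection. A CGR is a cluster of at
## least 4 interleaved intrachromosomal SVs (8 breakpoints): connected
## component of the "interleaving" graph, where two SVs are interleaved
## when their breakpoint intervals partially overlap (overlap > 0, neither
## contains the other) -- the interleaving semantics used by
## chromothripsis callers. Clusters on different chromosomes are linked
## into multi-chromosomal CGRs by direct translocations or by
## translocation enrichment (one-sided Fisher, BH-adjusted per tumor).

#' Are two intrachromosomal SVs interleaved?
#'
#' Intervals `[pos1, pos2]` partially overlap: positive overlap and
#' neither interval contains the other. SVs on different chromosomes are
#' never interleaved (returns `FALSE`, not an error).
#'
#' @param a,b single-row SV call tables (intrachromosomal).
#' @return logical scalar.
#' @export
interleaved <- function(a, b) {
  if (a$chrom1 != b$chrom1 || a$chrom1 != a$chrom2 || b$chrom1 != b$chrom2) {
    return(FALSE)
  }
  overlap <- min(a$pos2, b$pos2) - max(a$pos1, b$pos1)
  contains <- (a$pos1 <= b$pos1 && a$pos2 >= b$pos2) ||
    (b$pos1 <= a$pos1 && b$pos2 >= a$pos2)
  overlap > 0 && !contains
}

# Interleaving components among intrachromosomal SVs of one chromosome,
# by sweep: sort by start; only pairs whose intervals can overlap are
# examined. Returns an integer component id per row of `sv`.
interleave_components <- function(sv) {
  n <- nrow(sv)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(sv$pos1, sv$pos2)
  for (ii in seq_along(ord)[-1]) {
    i <- ord[ii]
    for (jj in rev(seq_len(ii - 1))) {
      j <- ord[jj]
      if (sv$pos2[j] <= sv$pos1[i]) next
      overlap <- min(sv$pos2[i], sv$pos2[j]) - max(sv$pos1[i], sv$pos1[j])
      contains <- (sv$pos1[i] <= sv$pos1[j] && sv$pos2[i] >= sv$pos2[j]) ||
        (sv$pos1[j] <= sv$pos1[i] && sv$pos2[j] >= sv$pos2[i])
      if (overlap > 0 && !contains) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Detect CGR clusters of interleaved SVs
#'
#' Connected components of the interleaving graph with at least `min_svs`
#' members, per chromosome. The cluster footprint runs from the leftmost
#' to the rightmost member breakpoint. Translocations do not participate
#' in the interleaving graph (they link clusters; see
#' [link_multichromosomal()]).
#'
#' @param svs SV call table for one sample.
#' @param min_svs minimum interleaved SVs per cluster (default 4,
#'   i.e. 8 breakpoints).
#' @return list with `clusters` (`data.frame`: `cluster_id`, `chrom`,
#'   `start`, `end`, `n_svs`) and `members` (`data.frame`: `cluster_id`,
#'   `sv_id`).
#' @export
detect_clusters <- function(svs, min_svs = 4) {
  intra <- svs[svs$chrom1 == svs$chrom2, , drop = FALSE]
  clusters <- list(); members <- list()
  cid <- 0L
  for (ch in unique(intra$chrom1)) {
    s <- intra[intra$chrom1 == ch, , drop = FALSE]
    comp <- interleave_components(s)
    for (k in unique(comp)) {
      idx <- which(comp == k)
      if (length(idx) < min_svs) next
      cid <- cid + 1L
      id <- sprintf("cgr%02d", cid)
      clusters[[cid]] <- data.frame(
        cluster_id = id, chrom = ch,
        start = min(s$pos1[idx]), end = max(s$pos2[idx]),
        n_svs = length(idx), stringsAsFactors = FALSE
      )
      members[[cid]] <- data.frame(cluster_id = id, sv_id = s$id[idx],
                                   stringsAsFactors = FALSE)
    }
  }
  if (!cid) {
    return(list(
      clusters = data.frame(cluster_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            n_svs = integer(), stringsAsFactors = FALSE),
      members = data.frame(cluster_id = character(), sv_id = character(),
                           stringsAsFactors = FALSE)
    ))
  }
  list(clusters = do.call(rbind, clusters), members = do.call(rbind, members))
}

#' Link CGR clusters across chromosomes
#'
#' Two linking rules, closed under union-find:
#' \itemize{
#' \item direct: a translocation with one breakpoint inside each of two
#'   clusters' footprints joins them;
#' \item enrichment: for each chromosome pair (i, j) with at least one
#'   translocation, a one-sided Fisher exact test on the 2x2 table
#'   `[t_ij, t_i. - t_ij; t_.j - t_ij, T - t_i. - t_.j + t_ij]` (t =
#'   translocation events; T = total in the tumor), BH-adjusted across the
#'   tested pairs within the tumor; clusters on i and j are joined if
#'   `q < alpha`.
#' }
#'
#' @param clusters output of [detect_clusters()].
#' @param translocations SV call table of the sample's translocations
#'   (`svtype == "TRA"`); other rows are ignored.
#' @param alpha q-value threshold for the enrichment rule (default 0.01).
#' @return list with `groups` (`data.frame`: `cluster_id`, `group_id`) and
#'   `links` (`data.frame`: chromosome pair, `t_ij`, `p`, `q`, `rule`).
#' @export
link_multichromosomal <- function(clusters, translocations, alpha = 0.01) {
  cl <- clusters$clusters
  tra <- translocations[translocations$svtype == "TRA", , drop = FALSE]
  n <- nrow(cl)
  parent <- seq_len(max(n, 1L))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  join <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  links <- list()
  if (n && nrow(tra)) {
    inside <- function(chrom, pos) {
      which(cl$chrom == chrom & pos >= cl$start & pos <= cl$end)
    }
    # rule 1: direct translocation between two footprints
    for (t in seq_len(nrow(tra))) {
      a <- inside(tra$chrom1[t], tra$pos1[t])
      b <- inside(tra$chrom2[t], tra$pos2[t])
      for (i in a) for (j in b) {
        if (cl$chrom[i] != cl$chrom[j]) {
          join(i, j)
          links[[length(links) + 1]] <- data.frame(
            chrom_a = cl$chrom[i], chrom_b = cl$chrom[j],
            t_ij = NA_integer_, p = NA_real_, q = NA_real_,
            rule = "direct", stringsAsFactors = FALSE
          )
        }
      }
    }
    # rule 2: translocation enrichment between chromosome pairs
    total <- nrow(tra)
    chroms <- sort(unique(c(tra$chrom1, tra$chrom2)))
    per_chrom <- vapply(chroms, function(ch) {
      sum(tra$chrom1 == ch) + sum(tra$chrom2 == ch)
    }, 0L)
    names(per_chrom) <- chroms
    pair_key <- paste(pmin(tra$chrom1, tra$chrom2),
                      pmax(tra$chrom1, tra$chrom2))
    tab <- table(pair_key)
    pairs <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    if (!is.null(pairs)) {
      p <- vapply(seq_len(nrow(pairs)), function(k) {
        tij <- as.integer(tab[k])
        ti <- per_chrom[pairs[k, 1]]
        tj <- per_chrom[pairs[k, 2]]
        fisher_2x2(tij, ti - tij, tj - tij, total - ti - tj + tij,
                   sided = "greater")
      }, 0)
      q <- bh_adjust(p)
      for (k in seq_len(nrow(pairs))) {
        ci <- which(cl$chrom == pairs[k, 1])
        cj <- which(cl$chrom == pairs[k, 2])
        joined <- q[k] < alpha && length(ci) && length(cj)
        if (joined) for (i in ci) for (j in cj) join(i, j)
        links[[length(links) + 1]] <- data.frame(
          chrom_a = pairs[k, 1], chrom_b = pairs[k, 2],
          t_ij = as.integer(tab[k]), p = p[k], q = q[k],
          rule = if (joined) "enrichment" else "enrichment_ns",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  groups <- data.frame(
    cluster_id = cl$cluster_id,
    group_id = if (n) {
      roots <- vapply(seq_len(n), find, 0L)
      sprintf("mcgr%02d", match(roots, unique(roots)))
    } else character(0),
    stringsAsFactors = FALSE
  )
  links <- if (length(links)) do.call(rbind, links) else data.frame(
    chrom_a = character(), chrom_b = character(), t_ij = integer(),
    p = numeric(), q = numeric(), rule = character(), stringsAsFactors = FALSE
  )
  list(groups = groups, links = links)
}

#' Fraction of SV breakpoints inside CGR footprints
#'
#' Every SV contributes two breakpoints; each breakpoint is counted
#' against the cluster footprints independently (a breakpoint is "inside"
#' if it falls within any footprint on its chromosome).
#'
#' @param svs SV call table.
#' @param clusters output of [detect_clusters()].
#' @return fraction in \[0, 1\], or `NA` when there are no breakpoints.
#' @export
breakpoint_fraction_in_cgr <- function(svs, clusters) {
  cl <- clusters$clusters
  n_bp <- 2L * nrow(svs)
  if (!n_bp) return(NA_real_)
  if (!nrow(cl)) return(0)
  inside <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      any(cl$chrom == chrom[i] & pos[i] >= cl$start & pos[i] <= cl$end)
    }, TRUE)
  }
  hits <- sum(inside(svs$chrom1, svs$pos1)) + sum(inside(svs$chrom2, svs$pos2))
  hits / n_bp
}
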
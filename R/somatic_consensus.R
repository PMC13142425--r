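## Somatic consensus filtering. Matched cases use two-caller intersections;
## tumor-only cases are filtered against a panel of normals: an SV is
## somatic only if every tumor-vs-control comparison labels it somatic and
## none labels it germline; SNVs additionally require VAF > 0.1.

#' Are two SV calls the same event?
#'
#' True iff the SV types match and, after canonical breakpoint ordering,
#' both breakpoint distances are strictly less than `tol` base pairs on
#' matching chromosomes. For translocations this means the unordered
#' chromosome pair must match with both breakpoints within tolerance.
#'
#' @param a,b single-row SV call tables (see [sv_calls()]).
#' @param tol breakpoint tolerance in bp (exclusive; default 10).
#' @return logical scalar. Symmetric; not guaranteed transitive, which is
#'   why cross-comparison identity uses single-linkage grouping
#'   ([sv_group()]).
#' @export
sv_equal <- function(a, b, tol = 10) {
  a$svtype == b$svtype &&
    a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
    abs(a$pos1 - b$pos1) < tol && abs(a$pos2 - b$pos2) < tol
}

#' Group SV calls across call sets by single-linkage on [sv_equal()]
#'
#' @param calls SV call table pooled over sets.
#' @param tol breakpoint tolerance in bp.
#' @return integer group id per row.
#' @export
sv_group <- function(calls, tol = 10) {
  n <- nrow(calls)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # bucket by (type, chrom pair) so only plausible pairs are compared
  bucket <- paste(calls$svtype, calls$chrom1, calls$chrom2)
  for (b in unique(bucket)) {
    idx <- which(bucket == b)
    if (length(idx) < 2) next
    idx <- idx[order(calls$pos1[idx])]
    for (i in seq_along(idx)[-1]) {
      for (j in rev(seq_len(i - 1))) {
        if (calls$pos1[idx[i]] - calls$pos1[idx[j]] >= tol) break
        if (abs(calls$pos2[idx[i]] - calls$pos2[idx[j]]) < tol) {
          ri <- find(idx[i]); rj <- find(idx[j])
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Tumor-only somatic SVs by panel-of-normals consensus
#'
#' Given one paired-analysis result per control (each labeling every SV
#' call `somatic` or `germline`), keep an SV iff it is labeled somatic in
#' all N comparisons and germline in none. Identity across comparisons is
#' single-linkage grouping under [sv_equal()].
#'
#' @param results list of `data.frame`s, one per control: SV call columns
#'   plus a `label` column with values `"somatic"`/`"germline"`.
#' @param tol breakpoint tolerance in bp.
#' @return SV call table of consensus somatic events (coordinates of the
#'   first comparison's record for each group).
#' @export
tumor_only_svs <- function(results, tol = 10) {
  if (!length(results)) stop("no paired-analysis results", call. = FALSE)
  n_comp <- length(results)
  pooled <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (!nrow(r)) return(NULL)
    r$.comparison <- i
    r
  }))
  if (is.null(pooled) || !nrow(pooled)) return(empty_sv_calls())
  grp <- sv_group(pooled, tol = tol)
  keep_groups <- vapply(split(seq_len(nrow(pooled)), grp), function(idx) {
    g <- pooled[idx, ]
    som <- unique(g$.comparison[g$label == "somatic"])
    length(som) == n_comp && !any(g$label == "germline")
  }, TRUE)
  first_idx <- vapply(split(seq_len(nrow(pooled)), grp), `[`, 0L, 1)
  out <- pooled[first_idx[keep_groups], , drop = FALSE]
  out$label <- NULL
  out$.comparison <- NULL
  rownames(out) <- NULL
  out
}

#' High-confidence SNVs from a two-caller matched analysis
#'
#' Exact-key intersection of the two callers' calls; caller labels are
#' merged on the retained records.
#'
#' @param calls_a,calls_b SNV call tables (see [snv_calls()]).
#' @return intersection with merged `callers`.
#' @export
consensus_snvs_paired <- function(calls_a, calls_b) {
  hit <- match(calls_a$key, calls_b$key)
  out <- calls_a[!is.na(hit), , drop = FALSE]
  other <- calls_b$callers[hit[!is.na(hit)]]
  out$callers <- vapply(seq_len(nrow(out)), function(i) {
    labs <- unlist(strsplit(c(out$callers[i], other[i]), ","))
    labs <- unique(labs[!is.na(labs) & nzchar(labs)])
    if (length(labs)) paste(labs, collapse = ",") else NA_character_
  }, "")
  rownames(out) <- NULL
  out
}

#' Tumor-only somatic SNVs
#'
#' Keep an SNV iff its VAF is strictly greater than `vaf_min` and its exact
#' key is absent from every germline control set.
#'
#' @param calls SNV call table with populated `vaf`.
#' @param control_sets list of SNV call tables from germline controls.
#' @param vaf_min strict VAF threshold (default 0.1).
#' @return filtered SNV call table.
#' @export
tumor_only_snvs <- function(calls, control_sets, vaf_min = 0.1) {
  control_keys <- unique(unlist(lapply(control_sets, function(s) s$key)))
  keep <- !is.na(calls$vaf) & calls$vaf > vaf_min &
    !(calls$key %in% control_keys)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Somatic indel consensus
#'
#' Matched mode: exact-key intersection of the two callers minus any indel
#' seen in a germline control. Tumor-only mode: the exact indel key must be
#' present in every tumor-vs-control comparison.
#'
#' @param caller_a_indels,caller_b_indels indel call tables (matched mode).
#' @param control_sets list of germline indel tables (matched mode) or of
#'   per-comparison somatic indel tables (tumor-only mode).
#' @param mode `"matched"` or `"tumor_only"`.
#' @return consensus indel call table.
#' @export
consensus_indels <- function(caller_a_indels = NULL, caller_b_indels = NULL,
                             control_sets = list(), mode = c("matched",
                                                             "tumor_only")) {
  mode <- match.arg(mode)
  if (mode == "matched") {
    both <- consensus_snvs_paired(caller_a_indels, caller_b_indels)
    control_keys <- unique(unlist(lapply(control_sets, function(s) s$key)))
    out <- both[!(both$key %in% control_keys), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (!length(control_sets)) {
    stop("tumor-only mode needs per-comparison indel sets", call. = FALSE)
  }
  keys <- Reduce(intersect, lapply(control_sets, function(s) s$key))
  out <- control_sets[[1]][control_sets[[1]]$key %in% keys, , drop = FALSE]
  rownames(out) <- NULL
  out
}
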
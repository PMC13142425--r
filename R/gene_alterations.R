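## Per-gene, per-tumor alteration calling from copy number, SV breakpoints
## and annotated small variants, with CGR co-occurrence flags and the
## cohort alteration matrix.

ALTERATION_CATEGORIES <- c("amplification", "focal_deletion",
                           "sv_breakpoint", "small_variant")

#' Impact filter for small variants
#'
#' Both conditions are required: impact in `impacts` and consequence in
#' `consequences`; a missense variant additionally requires the
#' deleteriousness flag.
#'
#' @param impacts allowed impact classes.
#' @param consequences allowed consequences.
#' @return list used by [call_small_variants()].
#' @export
impact_filter <- function(impacts = c("HIGH", "MODERATE"),
                          consequences = c("missense_variant", "stop_gained",
                                           "frameshift", "start_lost",
                                           "stop_lost")) {
  list(impacts = impacts, consequences = consequences)
}

#' Length-weighted average copy number over a gene body
#'
#' @param gene gene name present in `models`.
#' @param models `gene_models` object.
#' @param segments segment table with `copy_number`.
#' @return copies, or `NA` (with a warning) when no segment covers the
#'   gene body.
#' @export
gene_weighted_cn <- function(gene, models, segments) {
  g <- models$genes[models$genes$gene == gene, , drop = FALSE]
  if (!nrow(g)) stop("gene not in models: ", gene, call. = FALSE)
  s <- segments[segments$chrom == g$chrom, , drop = FALSE]
  if (!nrow(s)) {
    warning("no segment coverage for gene ", gene)
    return(NA_real_)
  }
  ov <- pmin(s$end, g$end) - pmax(s$start, g$start)
  keep <- ov > 0
  if (!any(keep)) {
    warning("no segment coverage for gene ", gene)
    return(NA_real_)
  }
  sum(ov[keep] * s$copy_number[keep]) / sum(ov[keep])
}

#' Length-weighted average copy number of a chromosome
#'
#' Computed over the (blacklist-filtered) segments of the chromosome.
#'
#' @param chrom chromosome name.
#' @param segments segment table with `copy_number`.
#' @return copies, or `NA` when the chromosome has no segments.
#' @export
chromosome_average_cn <- function(chrom, segments) {
  s <- segments[segments$chrom == chrom, , drop = FALSE]
  if (!nrow(s)) return(NA_real_)
  w <- s$end - s$start
  sum(w * s$copy_number) / sum(w)
}

#' Copy-number alteration call for one gene
#'
#' Amplification iff the gene's weighted copy number is `>= amp_min`
#' (default 5); focal deletion iff it is `<= homdel_max` (default 0.5)
#' AND at least `focal_delta` (default 0.5) copies below the chromosome
#' average (the focality condition). All boundaries inclusive.
#'
#' @param gene gene name.
#' @param gene_cn weighted gene copy number.
#' @param chrom_cn chromosome average copy number.
#' @param sample_id sample label.
#' @param amp_min,homdel_max,focal_delta thresholds.
#' @return one-row alteration call `data.frame`, or `NULL` if no call.
#' @export
call_gene_cn <- function(gene, gene_cn, chrom_cn, sample_id = NA_character_,
                         amp_min = 5, homdel_max = 0.5, focal_delta = 0.5) {
  if (is.na(gene_cn)) return(NULL)
  if (gene_cn >= amp_min) {
    return(alteration_row(gene, sample_id, "amplification",
                          sprintf("cn=%.3g", gene_cn)))
  }
  if (gene_cn <= homdel_max && !is.na(chrom_cn) &&
      (chrom_cn - gene_cn) >= focal_delta) {
    return(alteration_row(gene, sample_id, "focal_deletion",
                          sprintf("cn=%.3g;chrom_cn=%.3g", gene_cn, chrom_cn)))
  }
  NULL
}

alteration_row <- function(gene, sample_id, category, evidence) {
  data.frame(gene = gene, sample_id = sample_id, category = category,
             evidence = evidence, cgr_same_chromosome = NA,
             cgr_direct_overlap = NA, stringsAsFactors = FALSE)
}

#' SV disruption calls for one gene
#'
#' Intrachromosomal SVs are called iff at least one breakpoint falls in an
#' exon; translocations iff at least one breakpoint falls anywhere in the
#' gene body.
#'
#' @param gene gene name.
#' @param models `gene_models` object.
#' @param svs SV call table for the sample.
#' @param sample_id sample label.
#' @return alteration call rows (possibly zero).
#' @export
call_sv_disruption <- function(gene, models, svs, sample_id = NA_character_) {
  g <- models$genes[models$genes$gene == gene, , drop = FALSE]
  if (!nrow(g)) stop("gene not in models: ", gene, call. = FALSE)
  ex <- models$exons[models$exons$gene == gene, , drop = FALSE]
  in_exon <- function(chrom, pos) {
    chrom == g$chrom & vapply(pos, function(p) {
      any(p >= ex$start & p < ex$end)
    }, TRUE)
  }
  in_body <- function(chrom, pos) {
    chrom == g$chrom & pos >= g$start & pos < g$end
  }
  out <- list()
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    hit <- if (sv$svtype == "TRA") {
      in_body(sv$chrom1, sv$pos1) || in_body(sv$chrom2, sv$pos2)
    } else {
      in_exon(sv$chrom1, sv$pos1) || in_exon(sv$chrom2, sv$pos2)
    }
    if (hit) {
      out[[length(out) + 1]] <- alteration_row(
        gene, sample_id, "sv_breakpoint", paste0("sv=", sv$id))
    }
  }
  if (length(out)) do.call(rbind, out) else alteration_row(
    gene, sample_id, "sv_breakpoint", "")[0, ]
}

#' Impactful small-variant calls
#'
#' A variant is called iff its impact and consequence pass the filter;
#' missense variants additionally require the deleterious flag. Variants
#' without an annotation are skipped and counted.
#'
#' @param variants SNV/indel call table with `key`.
#' @param annotations impact table (see [read_impact_table()]).
#' @param filter from [impact_filter()].
#' @param sample_id sample label.
#' @return list with `calls` (alteration rows) and `n_unannotated`.
#' @export
call_small_variants <- function(variants, annotations,
                                filter = impact_filter(),
                                sample_id = NA_character_) {
  hit <- match(variants$key, annotations$key)
  n_unannotated <- sum(is.na(hit))
  out <- list()
  for (i in which(!is.na(hit))) {
    ann <- annotations[hit[i], ]
    ok <- ann$impact %in% filter$impacts &&
      ann$consequence %in% filter$consequences
    if (ok && ann$consequence == "missense_variant") {
      ok <- isTRUE(ann$deleterious)
    }
    if (ok) {
      out[[length(out) + 1]] <- alteration_row(
        ann$gene, sample_id, "small_variant", variants$key[i])
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    alteration_row("", "", "small_variant", "")[0, ]
  list(calls = calls, n_unannotated = n_unannotated)
}

#' Flag CGR co-occurrence on amplification calls
#'
#' `cgr_same_chromosome` is true iff any cluster footprint lies on the
#' gene's chromosome (mouse chromosomes are acrocentric, so the whole
#' chromosome stands in for the chromosome arm used in human analyses);
#' `cgr_direct_overlap` iff the gene body intersects a footprint.
#'
#' @param calls alteration call table (flags are set on amplification
#'   rows; other rows keep `NA`).
#' @param models `gene_models` object.
#' @param clusters [detect_clusters()] output for the same sample.
#' @return `calls` with flags filled in.
#' @export
flag_cgr_cooccurrence <- function(calls, models, clusters) {
  cl <- clusters$clusters
  for (i in which(calls$category == "amplification")) {
    g <- models$genes[models$genes$gene == calls$gene[i], , drop = FALSE]
    if (!nrow(g)) next
    same <- cl$chrom == g$chrom
    calls$cgr_same_chromosome[i] <- any(same)
    calls$cgr_direct_overlap[i] <- any(
      same & cl$start < g$end & cl$end > g$start
    )
  }
  calls
}

#' Cohort alteration matrix and per-gene frequencies
#'
#' Matrix cells carry the highest-priority category observed for that
#' gene/sample (`amplification > focal_deletion > sv_breakpoint >
#' small_variant`); frequencies count altered mice over eligible mice,
#' with multi-region mice contributing once (via their designated primary
#' sample) and engineered cases excluded from the denominator of their
#' engineered gene.
#'
#' @param calls alteration call table across samples.
#' @param sample_info `data.frame` with `sample_id`, `mouse_id` and a
#'   logical `is_primary` marking the one cohort-level sample per mouse.
#' @param gene_panel character vector of genes to report (rows).
#' @param engineered named list: gene -> mouse ids excluded from that
#'   gene's frequency denominator.
#' @return list with `matrix` (genes x mice, category strings or `""`),
#'   `frequency` (`data.frame`: gene, n_altered, n_eligible, frequency)
#'   and `unknown_genes` (calls whose gene is absent from the panel).
#' @export
build_alteration_matrix <- function(calls, sample_info, gene_panel,
                                    engineered = list()) {
  prim <- sample_info[sample_info$is_primary, , drop = FALSE]
  if (anyDuplicated(prim$mouse_id)) {
    stop("more than one primary sample for mouse ",
         prim$mouse_id[duplicated(prim$mouse_id)][1], call. = FALSE)
  }
  mice <- sort(unique(prim$mouse_id))
  unknown <- setdiff(unique(calls$gene), gene_panel)
  calls_p <- calls[calls$sample_id %in% prim$sample_id &
                     calls$gene %in% gene_panel, , drop = FALSE]
  calls_p$mouse_id <- prim$mouse_id[match(calls_p$sample_id, prim$sample_id)]
  mat <- matrix("", nrow = length(gene_panel), ncol = length(mice),
                dimnames = list(gene_panel, mice))
  if (nrow(calls_p)) {
    pri <- match(calls_p$category, ALTERATION_CATEGORIES)
    ord <- order(pri)
    for (i in rev(ord)) { # lowest priority written first, highest last
      mat[calls_p$gene[i], calls_p$mouse_id[i]] <- calls_p$category[i]
    }
  }
  freq <- do.call(rbind, lapply(gene_panel, function(g) {
    excluded <- if (!is.null(engineered[[g]])) engineered[[g]] else character(0)
    eligible <- setdiff(mice, excluded)
    altered <- sum(mat[g, eligible] != "")
    data.frame(gene = g, n_altered = altered, n_eligible = length(eligible),
               frequency = if (length(eligible)) altered / length(eligible)
                           else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(matrix = mat, frequency = freq, unknown_genes = unknown)
}
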
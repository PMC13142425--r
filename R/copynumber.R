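## Copy-number post-processing: blacklist filtering, conversion of relative
## log2 ratios to absolute copies given purity and ploidy, state
## classification, 1-Mb binning, cohort recurrence and profile similarity.

#' Copy-number state thresholds
#'
#' Defaults follow the lenient single-copy thresholds appropriate for
#' cohorts where many tumors have undergone whole-genome doubling (a
#' single-copy gain/loss after doubling appears as ~2.5/~1.5 copies when a
#' diploid genome is assumed), with stringent thresholds for amplification
#' and homozygous loss.
#'
#' @param gain_min minimum copies for a gain (default 2.5, inclusive).
#' @param loss_max maximum copies for a loss (default 1.5, inclusive).
#' @param amp_min minimum copies for an amplification (default 5).
#' @param homdel_max maximum copies for homozygous loss (default 0.5).
#' @return list of thresholds.
#' @export
cn_thresholds <- function(gain_min = 2.5, loss_max = 1.5, amp_min = 5,
                          homdel_max = 0.5) {
  if (!(homdel_max < loss_max && loss_max < gain_min && gain_min < amp_min)) {
    stop("thresholds must satisfy homdel_max < loss_max < gain_min < amp_min",
         call. = FALSE)
  }
  list(gain_min = gain_min, loss_max = loss_max, amp_min = amp_min,
       homdel_max = homdel_max)
}

#' Remove segments overlapping a blacklist
#'
#' A segment is removed iff at least `min_overlap` (default 20%) of its
#' length overlaps the union of the blacklist intervals, mirroring the
#' ENCODE-blacklist filter applied to low-mappability/high-signal regions.
#'
#' @param segments segment table (`chrom`, `start`, `end`, ...).
#' @param blacklist interval table (`chrom`, `start`, `end`).
#' @param min_overlap removal threshold as a fraction of segment length
#'   (inclusive).
#' @return the retained segments.
#' @export
filter_blacklist <- function(segments, blacklist, min_overlap = 0.20) {
  if (!nrow(segments) || !nrow(blacklist)) return(segments)
  validate_intervals(blacklist, what = "blacklist interval")
  seg_gr <- as_granges0(segments$chrom, segments$start, segments$end)
  bl_gr <- GenomicRanges::reduce(
    as_granges0(blacklist$chrom, blacklist$start, blacklist$end)
  )
  hits <- GenomicRanges::findOverlaps(seg_gr, bl_gr)
  ov <- IRanges::width(IRanges::pintersect(
    seg_gr[S4Vectors::queryHits(hits)], bl_gr[S4Vectors::subjectHits(hits)]
  ))
  ov_per_seg <- rep(0, nrow(segments))
  if (length(hits)) {
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    ov_per_seg[as.integer(names(agg))] <- as.numeric(agg)
  }
  frac <- ov_per_seg / (segments$end - segments$start)
  segments[frac < min_overlap, , drop = FALSE]
}

#' Absolute copy number from a relative log2 ratio
#'
#' Implements
#' `CN = (ploidy * 2^log2fc - 2 * (1 - purity)) / purity`,
#' i.e. the observed ratio is a purity-weighted mixture of the tumor copy
#' number and the diploid normal. Negative results are clamped to 0 with a
#' warning.
#'
#' @param log2_fold_change relative log2 copy ratio (e.g. CNVkit `log2`).
#' @param purity tumor cell fraction in (0, 1].
#' @param ploidy assumed tumor genome ploidy (default 2; cohort-wide
#'   analyses assume a diploid tumor genome).
#' @return absolute copy number (vectorized).
#' @export
#' @examples
#' absolute_cn(1, purity = 0.5) # 6
absolute_cn <- function(log2_fold_change, purity, ploidy = 2) {
  if (any(purity <= 0) || any(purity > 1)) {
    stop("purity must be in (0, 1]", call. = FALSE)
  }
  if (any(ploidy <= 0)) stop("ploidy must be > 0", call. = FALSE)
  cn <- (ploidy * 2^log2_fold_change - 2 * (1 - purity)) / purity
  if (any(cn < 0)) {
    warning("negative copy number clamped to 0")
    cn <- pmax(cn, 0)
  }
  cn
}

#' Relative log2 ratio from an absolute copy number
#'
#' Algebraic inverse of [absolute_cn()]; used by the simulator to distort
#' planted copy numbers by purity/ploidy, and in round-trip checks.
#'
#' @inheritParams absolute_cn
#' @param copy_number absolute tumor copies.
#' @param floor lower bound applied to the mixture ratio before taking
#'   log2, so fully deleted segments in a pure tumor stay finite.
#' @return log2 fold change.
#' @export
log2fc_from_cn <- function(copy_number, purity, ploidy = 2, floor = 2^-12) {
  if (any(purity <= 0) || any(purity > 1)) {
    stop("purity must be in (0, 1]", call. = FALSE)
  }
  ratio <- (copy_number * purity + 2 * (1 - purity)) / ploidy
  log2(pmax(ratio, floor))
}

#' Classify a copy number into a state
#'
#' Total, order-consistent partition of `[0, Inf)`: homozygous loss if
#' `<= homdel_max`, loss if `<= loss_max`, amplification if `>= amp_min`,
#' gain if `>= gain_min`, else neutral. All boundaries inclusive, matching
#' the >=/<= operators of the thresholds; amplification takes precedence
#' over gain and homozygous loss over loss.
#'
#' @param copy_number non-negative copies (vectorized).
#' @param thresholds from [cn_thresholds()].
#' @return character vector of states.
#' @export
classify_cn_state <- function(copy_number, thresholds = cn_thresholds()) {
  if (any(copy_number < 0, na.rm = TRUE)) {
    stop("copy_number must be >= 0", call. = FALSE)
  }
  ifelse(is.na(copy_number), NA_character_,
    ifelse(copy_number <= thresholds$homdel_max, "homozygous_loss",
      ifelse(copy_number <= thresholds$loss_max, "loss",
        ifelse(copy_number >= thresholds$amp_min, "amplification",
          ifelse(copy_number >= thresholds$gain_min, "gain", "neutral")))))
}

#' Bin absolute copy number into fixed-size genomic bins
#'
#' Each bin value is the length-weighted mean copy number of the segments
#' overlapping it; bins with no segment coverage are `NA` (missing, not
#' zero). Bins tile every chromosome of the genome in order.
#'
#' @param segments segment table with a `copy_number` column; segments must
#'   be non-overlapping within each chromosome.
#' @param genome chromosome-length table (see [default_genome()]).
#' @param bin_size bin width in bp (default 1 Mb).
#' @return `data.frame` with `chrom`, `start`, `end`, `copy_number`; the
#'   bin grid is identical for any input against the same genome.
#' @export
bin_copy_number <- function(segments, genome = default_genome(),
                            bin_size = 1e6) {
  if (any(is.na(segments$copy_number))) {
    stop("segments must carry copy_number (run absolute_cn first)",
         call. = FALSE)
  }
  # reject overlapping segments per chromosome
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch, call. = FALSE)
    }
  }
  bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + bin_size, genome$length[i]),
               stringsAsFactors = FALSE)
  }))
  bins$copy_number <- NA_real_
  if (nrow(segments)) {
    bin_gr <- as_granges0(bins$chrom, bins$start, bins$end)
    seg_gr <- as_granges0(segments$chrom, segments$start, segments$end)
    hits <- GenomicRanges::findOverlaps(bin_gr, seg_gr)
    if (length(hits)) {
      w <- IRanges::width(IRanges::pintersect(
        bin_gr[S4Vectors::queryHits(hits)], seg_gr[S4Vectors::subjectHits(hits)]
      ))
      cn <- segments$copy_number[S4Vectors::subjectHits(hits)]
      q <- S4Vectors::queryHits(hits)
      num <- tapply(w * cn, q, sum)
      den <- tapply(w, q, sum)
      bins$copy_number[as.integer(names(num))] <- as.numeric(num / den)
    }
  }
  bins
}

#' Per-bin gain/loss recurrence across tumors
#'
#' Counts, for every bin of a shared grid, the number of tumors whose
#' binned copy number qualifies as a gain or a loss. Callers are expected
#' to pass one profile per mouse (one designated primary sample for
#' multi-region cases).
#'
#' @param profiles named list of [bin_copy_number()] outputs on the same
#'   bin grid.
#' @param thresholds from [cn_thresholds()].
#' @param genome used to build an all-zero grid for an empty cohort.
#' @param bin_size bin width for the empty-cohort grid.
#' @return the bin grid with `gain_count` and `loss_count` columns.
#' @export
recurrence_profile <- function(profiles, thresholds = cn_thresholds(),
                               genome = default_genome(), bin_size = 1e6) {
  if (length(profiles) == 0) {
    grid <- bin_copy_number(
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 copy_number = numeric(), stringsAsFactors = FALSE),
      genome = genome, bin_size = bin_size)
    grid$copy_number <- NULL
    grid$gain_count <- 0L
    grid$loss_count <- 0L
    return(grid)
  }
  grid <- profiles[[1]][, c("chrom", "start", "end")]
  gain <- loss <- rep(0L, nrow(grid))
  for (p in profiles) {
    if (nrow(p) != nrow(grid) ||
        !all(p$chrom == grid$chrom & p$start == grid$start)) {
      stop("profiles are not on a shared bin grid", call. = FALSE)
    }
    st <- classify_cn_state(p$copy_number, thresholds)
    gain <- gain + as.integer(!is.na(st) & st %in% c("gain", "amplification"))
    loss <- loss + as.integer(!is.na(st) & st %in% c("loss", "homozygous_loss"))
  }
  grid$gain_count <- gain
  grid$loss_count <- loss
  grid
}

#' Cosine similarity of two binned copy-number profiles
#'
#' Computed over the bins non-missing in both profiles; missing bins are
#' excluded pairwise rather than imputed.
#'
#' @param profile_a,profile_b [bin_copy_number()] outputs on the same grid.
#' @return cosine similarity in \[0, 1\] for non-negative profiles.
#' @export
cosine_similarity <- function(profile_a, profile_b) {
  a <- profile_a$copy_number
  b <- profile_b$copy_number
  if (length(a) != length(b)) {
    stop("profiles are not on a shared bin grid", call. = FALSE)
  }
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no shared non-missing bins", call. = FALSE)
  a <- a[keep]; b <- b[keep]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero profile", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}
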
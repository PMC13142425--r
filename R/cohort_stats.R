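## Burden metrics and the small set of statistics used for cohort-level
## comparisons: Welch's t, Pearson chi-square on 2x2 tables (no continuity
## correction), Fisher's exact test, Benjamini-Hochberg adjustment and a
## cross-cohort per-gene enrichment scan.

#' Structural-variant breakpoint burden
#'
#' Sum of SV breakpoints on autosomes and chromosome X: each SV
#' contributes two breakpoints and each is counted iff it lies on an
#' included chromosome (Y and unplaced contigs are excluded).
#'
#' @param svs SV call table.
#' @param chromosomes chromosomes to count over (default autosomes + X).
#' @return breakpoint count.
#' @export
sv_burden <- function(svs, chromosomes = default_genome()$chrom) {
  sum(svs$chrom1 %in% chromosomes) + sum(svs$chrom2 %in% chromosomes)
}

#' Tumor mutational burden
#'
#' Non-synonymous coding SNVs per megabase of coding territory.
#'
#' @param snvs SNV call table.
#' @param annotations impact table (see [read_impact_table()]) keyed like
#'   the calls; variants whose consequence is not in
#'   `nonsyn_consequences` are excluded.
#' @param coding_mb coding territory in megabases; typically the merged
#'   exon length of the gene models (see [coding_territory_mb()]).
#' @param nonsyn_consequences consequences counted as non-synonymous.
#' @return mutations per Mb.
#' @export
tmb <- function(snvs, annotations, coding_mb,
                nonsyn_consequences = c("missense_variant", "stop_gained",
                                        "frameshift", "start_lost",
                                        "stop_lost")) {
  if (coding_mb <= 0) stop("coding territory must be > 0", call. = FALSE)
  ann <- annotations[annotations$consequence %in% nonsyn_consequences, ,
                     drop = FALSE]
  sum(snvs$key %in% ann$key) / coding_mb
}

#' Coding territory of a gene-model set, in megabases
#'
#' Length of the union of all exons (overlaps merged).
#'
#' @param models `gene_models` object.
#' @return megabases.
#' @export
coding_territory_mb <- function(models) {
  e <- models$exons
  if (!nrow(e)) return(0)
  merged <- GenomicRanges::reduce(as_granges0(e$chrom, e$start, e$end))
  sum(IRanges::width(merged)) / 1e6
}

#' Welch's unequal-variance t test (two-sided)
#'
#' Welch statistic with Satterthwaite degrees of freedom. Degenerate
#' inputs (zero variance in both groups with equal means) return `t = 0`,
#' `p = 1` by convention.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs >= 2 observations", call. = FALSE)
  }
  va <- stats::var(sample_a) / length(sample_a)
  vb <- stats::var(sample_b) / length(sample_b)
  if (va + vb == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, df = NA_real_, p = 1))
    }
    return(list(t = Inf * sign(mean(sample_a) - mean(sample_b)),
                df = NA_real_, p = 0))
  }
  tstat <- (mean(sample_a) - mean(sample_b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(sample_a) - 1) + vb^2 / (length(sample_b) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with p from the
#' chi-square distribution on 1 degree of freedom. No Yates correction is
#' applied.
#'
#' @param a,b,c,d cell counts (row-wise: `a b / c d`).
#' @return list with `chi2`, `p`.
#' @export
#' @examples
#' chisq_2x2(12, 10, 11, 35)$p # ~0.0125
chisq_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) stop("zero margin in 2x2 table", call. = FALSE)
  chi2 <- n * (a * d - b * c)^2 / prod(m)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. Two-sided p sums the
#' probabilities of all tables at the observed margins whose point
#' probability is at most that of the observed table (minimum-likelihood
#' method); one-sided variants are tail sums in `a`.
#'
#' @param a,b,c,d cell counts (row-wise: `a b / c d`).
#' @param sided `"two.sided"`, `"greater"` (enrichment in `a`) or
#'   `"less"`.
#' @return p-value.
#' @export
fisher_2x2 <- function(a, b, c, d, sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0", call. = FALSE)
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- switch(sided,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[xs >= a]),
    less = sum(probs[xs <= a])
  )
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, reported in the
#' input order. Monotone and idempotent.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  if (!m) return(numeric(0))
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Cross-cohort per-gene alteration enrichment
#'
#' For each gene altered in at least `min_cases` samples of cohort B (the
#' reference cohort used for the sparse-count filter), a two-sided Fisher
#' exact test on altered/unaltered counts in the two cohorts, BH-adjusted
#' across the tested genes.
#'
#' @param matrix_a,matrix_b logical/0-1 gene x sample alteration matrices
#'   with row names in a shared gene namespace (orthologs already mapped).
#' @param min_cases minimum altered cases in cohort B for a gene to be
#'   tested (default 10, inclusive).
#' @return `data.frame`: gene, counts, odds direction, `p`, `q`.
#' @export
cross_cohort_enrichment <- function(matrix_a, matrix_b, min_cases = 10) {
  genes <- intersect(rownames(matrix_a), rownames(matrix_b))
  if (!length(genes)) stop("no genes shared between cohorts", call. = FALSE)
  na <- ncol(matrix_a); nb <- ncol(matrix_b)
  alt_b <- rowSums(matrix_b[genes, , drop = FALSE] != 0)
  tested <- genes[alt_b >= min_cases]
  if (!length(tested)) {
    return(data.frame(gene = character(), alt_a = integer(),
                      alt_b = integer(), direction = character(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  }
  alt_a <- rowSums(matrix_a[tested, , drop = FALSE] != 0)
  p <- vapply(seq_along(tested), function(i) {
    fisher_2x2(alt_a[i], na - alt_a[i], alt_b[tested[i]],
               nb - alt_b[tested[i]], sided = "two.sided")
  }, 0)
  data.frame(
    gene = tested, alt_a = as.integer(alt_a),
    alt_b = as.integer(alt_b[tested]),
    direction = ifelse(alt_a / na >= alt_b[tested] / nb, "enriched_in_a",
                       "depleted_in_a"),
    p = p, q = bh_adjust(p), stringsAsFactors = FALSE
  )
}
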
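#' Default mouse-scale genome model
#'
#' Chromosome-length table used throughout the package: 19 autosomes plus
#' chromosome X with mouse-scale lengths (all chromosomes acrocentric, as in
#' the mouse). Lengths are approximate megabase-scale values; any table with
#' columns `chrom` and `length` can be supplied instead wherever a `genome`
#' argument is accepted.
#'
#' @return A `data.frame` with columns `chrom` (character, "chr"-prefixed)
#'   and `length` (integer base pairs).
#' @export
#' @examples
#' g <- default_genome()
#' head(g)
default_genome <- function() {
  data.frame(
    chrom = paste0("chr", c(1:19, "X")),
    length = as.numeric(c(
      195e6, 182e6, 160e6, 157e6, 152e6, 150e6, 145e6, 130e6, 124e6, 130e6,
      122e6, 120e6, 120e6, 125e6, 104e6, 98e6, 95e6, 91e6, 61e6, 169e6
    )),
    stringsAsFactors = FALSE
  )
}

#' Normalize chromosome names to the "chr"-prefixed convention
#'
#' @param x character vector of chromosome names (e.g. `"1"`, `"chr1"`).
#' @param aliases optional named character vector mapping input names to
#'   canonical names, applied after prefixing.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(x, aliases = NULL) {
  x <- as.character(x)
  miss <- !startsWith(x, "chr")
  x[miss] <- paste0("chr", x[miss])
  if (!is.null(aliases)) {
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  x
}

# Rank chromosomes in genome order (unknown chromosomes sort last, by name).
chrom_rank <- function(chrom, genome = default_genome()) {
  m <- match(chrom, genome$chrom)
  m[is.na(m)] <- nrow(genome) + rank(chrom[is.na(m)], ties.method = "min")
  m
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

# Internal constructor for genomic intervals (0-based half-open).
validate_intervals <- function(df, genome = NULL, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("%s with invalid coordinates at row(s) %s (need 0 <= start < end)",
                 what, paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(genome)) {
    unk <- setdiff(unique(df$chrom), genome$chrom)
    if (length(unk)) {
      stop(sprintf("%s on chromosome(s) not in genome: %s",
                   what, paste(unk, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(df)
}

# data.frame -> GRanges under the internal 0-based half-open convention.
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
}
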
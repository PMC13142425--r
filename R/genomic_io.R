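## Readers/writers for the formats the pipeline touches. Everything inside
## the package uses one coordinate convention: 0-based half-open intervals
## and 0-based positions. Conversion to/from 1-based VCF POS happens only
## here, at the format boundary. BED and CNVkit-style segment files are
## already 0-based half-open and pass through unchanged.

SV_TYPES <- c("DEL", "DUP", "h2hINV", "t2tINV", "TRA")

#' Construct a structural-variant call table
#'
#' An SV call is a breakpoint pair with orientations. Breakpoints are stored
#' in canonical order: `(chrom1, pos1)` sorts before `(chrom2, pos2)` in
#' genome order, swapping ends (and their strands) if needed. The type is
#' derived from the breakend orientations for intrachromosomal events
#' (`+-` DEL-like, `-+` DUP-like, `++` head-to-head inversion, `--`
#' tail-to-tail inversion) and is `TRA` iff the chromosomes differ.
#'
#' @param chrom1,pos1,strand1 first breakend (0-based position).
#' @param chrom2,pos2,strand2 second breakend.
#' @param svtype optional; derived from orientation when `NULL`.
#' @param alt_reads,depth supporting read count (AD) and depth (DP); the
#'   allele fraction is `AD/DP` where both are given.
#' @param sample_id sample label, recycled.
#' @param id record identifiers; generated when `NULL`.
#' @return `data.frame` with one row per SV.
#' @export
sv_calls <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                     svtype = NULL, alt_reads = NA_real_, depth = NA_real_,
                     sample_id = NA_character_, id = NULL) {
  n <- length(pos1)
  df <- data.frame(
    id = if (is.null(id)) sprintf("sv%04d", seq_len(n)) else as.character(id),
    sample_id = rep_len(as.character(sample_id), n),
    chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
    strand1 = as.character(strand1),
    chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
    strand2 = as.character(strand2),
    alt_reads = rep_len(as.numeric(alt_reads), n),
    depth = rep_len(as.numeric(depth), n),
    stringsAsFactors = FALSE
  )
  df <- canonicalize_breakends(df)
  derived <- derive_sv_type(df)
  df$svtype <- if (is.null(svtype)) derived else as.character(rep_len(svtype, n))
  bad <- !df$svtype %in% SV_TYPES
  if (any(bad)) {
    stop("unknown SV type(s): ", paste(unique(df$svtype[bad]), collapse = ", "),
         call. = FALSE)
  }
  df$vaf <- ifelse(is.na(df$alt_reads) | is.na(df$depth) | df$depth == 0,
                   NA_real_, df$alt_reads / df$depth)
  df[, c("id", "sample_id", "chrom1", "pos1", "strand1",
         "chrom2", "pos2", "strand2", "svtype", "alt_reads", "depth", "vaf")]
}

canonicalize_breakends <- function(df) {
  r1 <- chrom_rank(df$chrom1)
  r2 <- chrom_rank(df$chrom2)
  swap <- r1 > r2 | (r1 == r2 & df$pos1 > df$pos2)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "strand1")]
    df[swap, c("chrom1", "pos1", "strand1")] <-
      df[swap, c("chrom2", "pos2", "strand2")]
    df[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  df
}

derive_sv_type <- function(df) {
  ifelse(df$chrom1 != df$chrom2, "TRA",
    ifelse(df$strand1 == "+" & df$strand2 == "-", "DEL",
      ifelse(df$strand1 == "-" & df$strand2 == "+", "DUP",
        ifelse(df$strand1 == "+", "h2hINV", "t2tINV"))))
}

empty_sv_calls <- function() {
  sv_calls(character(), numeric(), character(), character(), numeric(),
           character())
}

## ---- SV VCF (paired breakend records) --------------------------------------

# ALT breakend syntax encodes orientations:
#   (+,-) N[chr:p[   (+,+) N]chr:p]   (-,-) [chr:p[N   (-,+) ]chr:p]N
bnd_alt <- function(strand_local, strand_mate, chrom_mate, pos_mate_1based) {
  br <- if (strand_mate == "-") sprintf("[%s:%d[", chrom_mate, pos_mate_1based)
        else sprintf("]%s:%d]", chrom_mate, pos_mate_1based)
  if (strand_local == "+") paste0("N", br) else paste0(br, "N")
}

parse_bnd_alt <- function(alt) {
  m <- regexec("^([ACGTN]*)([][])([^:]+):([0-9]+)([][])([ACGTN]*)$", alt)
  g <- regmatches(alt, m)[[1]]
  if (!length(g)) return(NULL)
  base_first <- nzchar(g[2])
  list(
    strand_local = if (base_first) "+" else "-",
    strand_mate = if (g[3] == "[") "-" else "+",
    chrom_mate = g[4],
    pos_mate = as.numeric(g[5])
  )
}

#' Write structural variants as a VCF 4.2 breakend file
#'
#' Each SV is emitted as a pair of BND records linked by `MATEID`, with
#' `DP`/`AD` carried in the genotype column. Positions are converted from
#' the internal 0-based convention to 1-based VCF `POS`.
#'
#' @param calls SV call table from [sv_calls()].
#' @param path output file path.
#' @param sample_name genotype column label.
#' @export
write_sv_vcf <- function(calls, path, sample_name = "TUMOR") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  rows <- character(0)
  if (nrow(calls)) {
    fmt_count <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE))
    gt <- paste(fmt_count(calls$depth), fmt_count(calls$alt_reads), sep = ":")
    id1 <- paste0(calls$id, "_1"); id2 <- paste0(calls$id, "_2")
    alt1 <- mapply(bnd_alt, calls$strand1, calls$strand2,
                   calls$chrom2, calls$pos2 + 1L)
    alt2 <- mapply(bnd_alt, calls$strand2, calls$strand1,
                   calls$chrom1, calls$pos1 + 1L)
    mk <- function(chrom, pos, id, alt, mate, gt) {
      paste(chrom, format(pos + 1L, scientific = FALSE), id, "N", alt, ".",
            "PASS", paste0("SVTYPE=BND;MATEID=", mate), "DP:AD", gt, sep = "\t")
    }
    rows <- c(mk(calls$chrom1, calls$pos1, id1, alt1, id2, gt),
              mk(calls$chrom2, calls$pos2, id2, alt2, id1, gt))
    rows <- rows[order(rep(seq_len(nrow(calls)), 2))]
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read structural variants from VCF
#'
#' Accepts paired breakend records (`SVTYPE=BND` with `MATEID`) and typed
#' single-record dialects (`SVTYPE=DEL|DUP|INV|TRA` with `END` and a
#' `STRANDS` tag). Inversions are split into head-to-head (`++`) and
#' tail-to-tail (`--`) per the breakend orientations. 1-based `POS` is
#' converted to the internal 0-based convention.
#'
#' @param path VCF file path.
#' @param sample_id sample label to attach to the calls.
#' @return SV call table (see [sv_calls()]).
#' @export
read_sv_vcf <- function(path, sample_id = NA_character_) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_sv_calls())
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 8)) {
    stop("malformed VCF record at line(s) ",
         paste(which(nf < 8), collapse = ", "), call. = FALSE)
  }
  rec <- data.frame(
    chrom = vapply(f, `[`, "", 1), pos = as.numeric(vapply(f, `[`, "", 2)) - 1,
    id = vapply(f, `[`, "", 3), alt = vapply(f, `[`, "", 5),
    info = vapply(f, `[`, "", 8), stringsAsFactors = FALSE
  )
  gt <- vapply(seq_along(f), function(i) {
    if (nf[i] >= 10) paste(f[[i]][9], f[[i]][10], sep = "|") else NA_character_
  }, "")
  parse_gt <- function(g) {
    if (is.na(g)) return(c(NA_real_, NA_real_))
    kv <- strsplit(g, "|", fixed = TRUE)[[1]]
    keys <- strsplit(kv[1], ":", fixed = TRUE)[[1]]
    vals <- strsplit(kv[2], ":", fixed = TRUE)[[1]]
    dp <- suppressWarnings(as.numeric(vals[match("DP", keys)]))
    ad <- suppressWarnings(as.numeric(vals[match("AD", keys)]))
    # multi-allele AD (ref,alt): take the alt count
    if (is.na(ad) && !is.na(match("AD", keys))) {
      parts <- strsplit(vals[match("AD", keys)], ",", fixed = TRUE)[[1]]
      ad <- suppressWarnings(as.numeric(parts[length(parts)]))
    }
    c(dp, ad)
  }
  gtm <- t(vapply(gt, parse_gt, numeric(2)))
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(g) if (length(g)) g[2] else NA_character_, "")
  }
  svtype <- info_get(rec$info, "SVTYPE")
  if (anyNA(svtype)) {
    stop("record(s) without SVTYPE: ",
         paste(rec$id[is.na(svtype)], collapse = ", "), call. = FALSE)
  }
  out <- list()
  is_bnd <- svtype == "BND"
  if (any(is_bnd)) {
    mate <- info_get(rec$info[is_bnd], "MATEID")
    bnd <- rec[is_bnd, , drop = FALSE]
    bnd$mate <- mate
    orphan <- !(bnd$mate %in% bnd$id)
    if (any(orphan)) {
      stop("orphan breakend record(s), mate not found: ",
           paste(bnd$id[orphan], collapse = ", "), call. = FALSE)
    }
    # keep one record per junction: the lexicographically first of each pair
    keep <- bnd$id < bnd$mate
    first <- bnd[keep, , drop = FALSE]
    gfirst <- gtm[is_bnd, , drop = FALSE][keep, , drop = FALSE]
    parsed <- lapply(first$alt, parse_bnd_alt)
    bad <- vapply(parsed, is.null, TRUE)
    if (any(bad)) {
      stop("unparseable breakend ALT in record(s): ",
           paste(first$id[bad], collapse = ", "), call. = FALSE)
    }
    out$bnd <- sv_calls(
      chrom1 = first$chrom, pos1 = first$pos,
      strand1 = vapply(parsed, `[[`, "", "strand_local"),
      chrom2 = vapply(parsed, `[[`, "", "chrom_mate"),
      pos2 = vapply(parsed, function(p) p$pos_mate - 1, 0),
      strand2 = vapply(parsed, `[[`, "", "strand_mate"),
      depth = gfirst[, 1], alt_reads = gfirst[, 2],
      sample_id = sample_id, id = sub("_1$", "", first$id)
    )
  }
  typed <- !is_bnd
  if (any(typed)) {
    tt <- svtype[typed]
    known <- c("DEL", "DUP", "INV", "TRA")
    if (!all(tt %in% known)) {
      stop("unknown SVTYPE: ", paste(setdiff(tt, known), collapse = ", "),
           call. = FALSE)
    }
    trec <- rec[typed, , drop = FALSE]
    tgt <- gtm[typed, , drop = FALSE]
    end2 <- as.numeric(info_get(trec$info, "END")) - 1
    chr2 <- info_get(trec$info, "CHR2")
    chr2[is.na(chr2)] <- trec$chrom[is.na(chr2)]
    strands <- info_get(trec$info, "STRANDS")
    s1 <- substr(strands, 1, 1); s2 <- substr(strands, 2, 2)
    dflt <- list(DEL = c("+", "-"), DUP = c("-", "+"), TRA = c("+", "-"))
    for (i in seq_along(tt)) {
      if (is.na(strands[i]) || !nzchar(s1[i])) {
        if (tt[i] == "INV") {
          stop("typed INV record without STRANDS info: ", trec$id[i],
               call. = FALSE)
        }
        s1[i] <- dflt[[tt[i]]][1]; s2[i] <- dflt[[tt[i]]][2]
      }
    }
    if (anyNA(end2)) {
      stop("typed SV record without END: ",
           paste(trec$id[is.na(end2)], collapse = ", "), call. = FALSE)
    }
    out$typed <- sv_calls(
      chrom1 = trec$chrom, pos1 = trec$pos, strand1 = s1,
      chrom2 = chr2, pos2 = end2, strand2 = s2,
      depth = tgt[, 1], alt_reads = tgt[, 2],
      sample_id = sample_id, id = trec$id
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- SNV / indel VCF -------------------------------------------------------

#' Construct an SNV/indel call table
#'
#' Keyed by `(chrom, pos, ref, alt)` with 0-based positions. `hq_alt_count`
#' is the number of supporting reads passing the high-quality thresholds
#' (mapping quality >= 30, base quality >= 20) used for multi-region
#' presence calls; it defaults to `alt_count`.
#'
#' @param chrom,pos,ref,alt variant key (0-based position).
#' @param depth,alt_count DP and alt-supporting AD.
#' @param callers comma-separated caller labels per variant.
#' @param hq_alt_count high-quality alt read count.
#' @param sample_id sample label.
#' @return `data.frame`, one row per variant, with a `key` column and
#'   `vaf = alt_count/depth`.
#' @export
snv_calls <- function(chrom, pos, ref, alt, depth = NA_real_,
                      alt_count = NA_real_, callers = NA_character_,
                      hq_alt_count = NULL, sample_id = NA_character_) {
  n <- length(pos)
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = as.character(chrom), pos = as.numeric(pos),
    ref = as.character(ref), alt = as.character(alt),
    depth = rep_len(as.numeric(depth), n),
    alt_count = rep_len(as.numeric(alt_count), n),
    callers = rep_len(as.character(callers), n),
    stringsAsFactors = FALSE
  )
  df$hq_alt_count <- if (is.null(hq_alt_count)) df$alt_count
                     else rep_len(as.numeric(hq_alt_count), n)
  bad <- which(!is.na(df$alt_count) & !is.na(df$depth) &
                 (df$alt_count < 0 | df$alt_count > df$depth))
  if (length(bad)) {
    stop("alt_count outside [0, depth] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$vaf <- ifelse(is.na(df$depth) | df$depth == 0, NA_real_,
                   df$alt_count / df$depth)
  df$key <- snv_key(df)
  df
}

#' @rdname snv_calls
#' @param x an SNV call table.
#' @export
snv_key <- function(x) {
  paste(x$chrom, format(x$pos, scientific = FALSE, trim = TRUE), x$ref, x$alt,
        sep = ":")
}

#' Write SNVs/indels as VCF 4.2
#'
#' @param calls table from [snv_calls()].
#' @param path output path.
#' @param sample_name genotype column label.
#' @export
write_snv_vcf <- function(calls, path, sample_name = "TUMOR") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Callers reporting the variant\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=HQAD,Number=1,Type=Integer,Description=\"High-quality alt reads (MQ>=30, BQ>=20)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  rows <- character(0)
  if (nrow(calls)) {
    fmt_n <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE))
    info <- ifelse(is.na(calls$callers), ".",
                   paste0("CALLERS=", calls$callers))
    ad <- ifelse(is.na(calls$depth) | is.na(calls$alt_count), ".",
                 paste(fmt_n(calls$depth - calls$alt_count),
                       fmt_n(calls$alt_count), sep = ","))
    gt <- paste(fmt_n(calls$depth), ad, fmt_n(calls$hq_alt_count), sep = ":")
    rows <- paste(calls$chrom, format(calls$pos + 1, scientific = FALSE,
                                      trim = TRUE),
                  ".", calls$ref, calls$alt, ".", "PASS", info,
                  "DP:AD:HQAD", gt, sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read SNVs/indels from VCF 4.2
#'
#' @param path VCF path.
#' @param sample_id sample label attached to the calls.
#' @return table as from [snv_calls()].
#' @export
read_snv_vcf <- function(path, sample_id = NA_character_) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(snv_calls(character(), numeric(), character(), character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[`, "", i)
  info <- get(8)
  m <- regmatches(info, regexec("(?:^|;)CALLERS=([^;]*)", info))
  callers <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, "")
  dp <- rep(NA_real_, length(f)); ad <- dp; hq <- dp
  has_gt <- lengths(f) >= 10
  for (i in which(has_gt)) {
    keys <- strsplit(f[[i]][9], ":", fixed = TRUE)[[1]]
    vals <- strsplit(f[[i]][10], ":", fixed = TRUE)[[1]]
    dp[i] <- suppressWarnings(as.numeric(vals[match("DP", keys)]))
    adraw <- vals[match("AD", keys)]
    if (!is.na(adraw) && adraw != ".") {
      parts <- strsplit(adraw, ",", fixed = TRUE)[[1]]
      ad[i] <- suppressWarnings(as.numeric(parts[length(parts)]))
    }
    hq[i] <- suppressWarnings(as.numeric(vals[match("HQAD", keys)]))
  }
  hq[is.na(hq)] <- ad[is.na(hq)]
  snv_calls(chrom = get(1), pos = as.numeric(get(2)) - 1,
            ref = get(4), alt = get(5), depth = dp, alt_count = ad,
            callers = callers, hq_alt_count = hq, sample_id = sample_id)
}

## ---- segments, BED, gene models, impact table ------------------------------

#' Read copy-number segments (CNVkit .cns-style)
#'
#' Tab-separated with a header containing at least `chromosome`, `start`,
#' `end` and `log2`; extra columns are ignored. Coordinates are 0-based
#' half-open as emitted by CNVkit.
#'
#' @param path file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`,
#'   `log2_fold_change` and `copy_number` (NA until inferred).
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chromosome", "start", "end", "log2")
  if (!all(need %in% names(df))) {
    stop("segment file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    chrom = normalize_chrom(df$chromosome),
    start = as.numeric(df$start), end = as.numeric(df$end),
    log2_fold_change = as.numeric(df$log2),
    copy_number = if ("copy_number" %in% names(df))
      as.numeric(df$copy_number) else NA_real_,
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$end <= out$start)
  if (length(bad)) {
    stop("invalid segment coordinates at data line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write copy-number segments in the .cns-style dialect
#' @param segments segment table.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  df <- data.frame(
    chromosome = segments$chrom,
    start = format(segments$start, scientific = FALSE, trim = TRUE),
    end = format(segments$end, scientific = FALSE, trim = TRUE),
    gene = "-",
    log2 = format(segments$log2_fold_change, digits = 10),
    stringsAsFactors = FALSE
  )
  if (!is.null(segments$copy_number) && !all(is.na(segments$copy_number))) {
    df$copy_number <- format(segments$copy_number, digits = 10)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3 file of intervals
#'
#' @param path BED file (no header; 0-based half-open, as BED).
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "[ \t]+")
  df <- data.frame(
    chrom = normalize_chrom(vapply(f, `[`, "", 1)),
    start = as.numeric(vapply(f, `[`, "", 2)),
    end = as.numeric(vapply(f, `[`, "", 3)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$end <= df$start)
  if (length(bad)) {
    stop("invalid BED coordinates at line(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read gene models from BED12
#'
#' Block fields give the exon structure; exons are validated to lie within
#' the gene body.
#'
#' @param path BED12 file.
#' @return object of class `gene_models`: list with `genes` (gene, chrom,
#'   strand, start, end) and `exons` (gene, chrom, start, end).
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 12)) {
    stop("BED12 requires 12 fields; short line(s) ",
         paste(which(nf < 12), collapse = ", "), call. = FALSE)
  }
  genes <- data.frame(
    gene = vapply(f, `[`, "", 4),
    chrom = normalize_chrom(vapply(f, `[`, "", 1)),
    strand = vapply(f, `[`, "", 6),
    start = as.numeric(vapply(f, `[`, "", 2)),
    end = as.numeric(vapply(f, `[`, "", 3)),
    stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(seq_along(f), function(i) {
    n_blocks <- as.integer(f[[i]][10])
    sizes <- as.numeric(strsplit(f[[i]][11], ",")[[1]])[seq_len(n_blocks)]
    starts <- as.numeric(strsplit(f[[i]][12], ",")[[1]])[seq_len(n_blocks)]
    data.frame(gene = genes$gene[i], chrom = genes$chrom[i],
               start = genes$start[i] + starts,
               end = genes$start[i] + starts + sizes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(exons)) {
    exons <- data.frame(gene = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    e <- exons[exons$gene == genes$gene[i], , drop = FALSE]
    if (nrow(e) && (min(e$start) < genes$start[i] || max(e$end) > genes$end[i])) {
      stop("exons outside gene body for gene ", genes$gene[i], call. = FALSE)
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models as BED12
#' @param models `gene_models` object.
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  rows <- vapply(seq_len(nrow(g)), function(i) {
    e <- models$exons[models$exons$gene == g$gene[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    paste(g$chrom[i],
          format(g$start[i], scientific = FALSE, trim = TRUE),
          format(g$end[i], scientific = FALSE, trim = TRUE),
          g$gene[i], 0, g$strand[i],
          format(g$start[i], scientific = FALSE, trim = TRUE),
          format(g$start[i], scientific = FALSE, trim = TRUE),
          "0", nrow(e),
          paste0(paste(format(e$end - e$start, scientific = FALSE,
                              trim = TRUE), collapse = ","), ","),
          paste0(paste(format(e$start - g$start[i], scientific = FALSE,
                              trim = TRUE), collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Read a variant impact annotation table
#'
#' Tab-separated with header: `key` (variant key `chrom:pos:ref:alt`),
#' `gene`, `consequence`, `impact` (one of HIGH/MODERATE/LOW/MODIFIER) and
#' an optional logical `deleterious` column.
#'
#' @param path file path.
#' @return `data.frame` of annotations.
#' @export
read_impact_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("key", "gene", "consequence", "impact")
  if (!all(need %in% names(df))) {
    stop("impact table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok <- df$impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (!all(ok)) {
    stop("invalid impact value(s) at line(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  if (is.null(df$deleterious)) df$deleterious <- NA
  df$deleterious <- as.logical(df$deleterious)
  df
}
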
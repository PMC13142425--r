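## Synthetic multi-sample tumor cohort generator with known ground truth.
## The generator states a world: one mouse sampled at n_samples tumor
## regions related by a clone tree (truncal mutations on the root branch,
## shared mutations on internal branches, private mutations on leaf
## branches), planted CGRs that are truncal (complex rearrangements are
## established early, before clonal diversification), purity/ploidy
## distorted log2 copy ratios, and a panel of normals carrying common
## germline variants. Noise knobs (breakpoint jitter, call dropout,
## germline leakage into tumor call sets) default to 0 so oracle tests can
## run on the noise-free world; each is enabled explicitly per test.
## A single RNG stream is used, seeded once from the config.

#' Specification of one planted complex genomic rearrangement
#'
#' @param chromosomes chromosome name(s); `multichromosomal` style needs
#'   at least 2 and at least 4 interleaved SVs per chromosome.
#' @param n_svs number of interleaved intrachromosomal SVs (>= 4 so the
#'   planted cluster is detectable; translocations emitted by the
#'   multichromosomal style are additional).
#' @param style `"chromothripsis"` (oscillating copy number),
#'   `"bfb"` (foldback inversion, escalating amplification, terminal
#'   loss) or `"multichromosomal"` (clusters on several chromosomes
#'   joined by translocations).
#' @param amplified_gene optional gene (must exist in the cohort gene
#'   models) whose footprint is raised to `target_copies`.
#' @param target_copies copy number of the amplified gene footprint.
#' @return validated `cgr_spec` list.
#' @export
cgr_spec <- function(chromosomes, n_svs = 6,
                     style = c("chromothripsis", "bfb", "multichromosomal"),
                     amplified_gene = NULL, target_copies = 8) {
  style <- match.arg(style)
  if (n_svs < 4) stop_field("n_svs", "must be >= 4 for a detectable cluster")
  if (style == "multichromosomal") {
    if (length(chromosomes) < 2) {
      stop_field("chromosomes", "multichromosomal style needs >= 2 chromosomes")
    }
    if (n_svs < 4 * length(chromosomes)) {
      stop_field("n_svs", "multichromosomal style needs >= 4 SVs per chromosome")
    }
  } else if (length(chromosomes) != 1) {
    stop_field("chromosomes", paste(style, "style uses exactly 1 chromosome"))
  }
  if (target_copies <= 0) stop_field("target_copies", "must be > 0")
  structure(list(chromosomes = chromosomes, n_svs = n_svs, style = style,
                 amplified_gene = amplified_gene,
                 target_copies = target_copies), class = "cgr_spec")
}

#' Synthetic cohort configuration
#'
#' Defaults describe a typical multi-region design: 4 regions of one
#' tumor at purity 0.7 and 100x depth, 50 truncal / 20 shared (per
#' internal branch) / 10 private (per sample) SNVs, 12 background SVs and
#' a panel of 17 normals.
#'
#' @param n_samples tumor regions sampled from the mouse.
#' @param n_truncal_snvs,n_shared_snvs,n_private_snvs SNV counts on the
#'   root branch, each internal branch, and each leaf branch.
#' @param n_background_svs scattered SVs outside any CGR, assigned
#'   round-robin over the clone-tree branches.
#' @param cgr_specs list of [cgr_spec()]s; specs must use disjoint
#'   chromosomes.
#' @param purity_per_sample tumor cell fraction in (0, 1], recycled.
#' @param ploidy assumed baseline tumor ploidy.
#' @param depth_mean sequencing depth of the tumor samples.
#' @param n_normals panel-of-normals size.
#' @param n_germline common germline SNVs carried by every normal.
#' @param breakpoint_jitter sd (bp) of gaussian jitter on emitted SV
#'   breakpoints (noise knob, default 0).
#' @param dropout_rate per-sample probability that a carried call is
#'   dropped (noise knob, default 0).
#' @param germline_leakage number of common germline SNVs injected into
#'   each tumor call set (noise knob, default 0).
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @param genome chromosome-length table.
#' @param genes `gene_models` object (default [default_gene_models()]).
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 4, n_truncal_snvs = 50,
                       n_shared_snvs = 20, n_private_snvs = 10,
                       n_background_svs = 12, cgr_specs = list(),
                       purity_per_sample = 0.7, ploidy = 2,
                       depth_mean = 100, n_normals = 17, n_germline = 200,
                       breakpoint_jitter = 0, dropout_rate = 0,
                       germline_leakage = 0, seed = 1,
                       genome = default_genome(),
                       genes = default_gene_models()) {
  counts <- list(n_samples = n_samples, n_truncal_snvs = n_truncal_snvs,
                 n_shared_snvs = n_shared_snvs,
                 n_private_snvs = n_private_snvs,
                 n_background_svs = n_background_svs, n_normals = n_normals,
                 n_germline = n_germline, germline_leakage = germline_leakage)
  for (f in names(counts)) {
    if (length(counts[[f]]) != 1 || is.na(counts[[f]]) || counts[[f]] < 0) {
      stop_field(f, "must be a non-negative count")
    }
  }
  if (n_samples < 1) stop_field("n_samples", "must be >= 1")
  if (any(purity_per_sample <= 0 | purity_per_sample > 1)) {
    stop_field("purity_per_sample", "must be in (0, 1]")
  }
  if (ploidy <= 0) stop_field("ploidy", "must be > 0")
  if (depth_mean <= 0) stop_field("depth_mean", "must be > 0")
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop_field("dropout_rate", "must be in [0, 1]")
  }
  for (sp in cgr_specs) {
    if (!inherits(sp, "cgr_spec")) {
      stop_field("cgr_specs", "entries must be cgr_spec objects")
    }
    missing <- setdiff(sp$chromosomes, genome$chrom)
    if (length(missing)) {
      stop_field("cgr_specs", paste("chromosome not in genome:",
                                    paste(missing, collapse = ", ")))
    }
  }
  used <- unlist(lapply(cgr_specs, `[[`, "chromosomes"))
  if (anyDuplicated(used)) {
    stop_field("cgr_specs", "specs must use disjoint chromosomes")
  }
  structure(list(
    n_samples = n_samples, n_truncal_snvs = n_truncal_snvs,
    n_shared_snvs = n_shared_snvs, n_private_snvs = n_private_snvs,
    n_background_svs = n_background_svs, cgr_specs = cgr_specs,
    purity_per_sample = rep_len(purity_per_sample, n_samples),
    ploidy = ploidy, depth_mean = depth_mean, n_normals = n_normals,
    n_germline = n_germline, breakpoint_jitter = breakpoint_jitter,
    dropout_rate = dropout_rate, germline_leakage = germline_leakage,
    seed = seed, genome = genome, genes = genes
  ), class = "sim_config")
}

#' Synthetic gene models for the default cohort
#'
#' A small panel of synthetic stand-ins for osteosarcoma-relevant mouse
#' genes (Myc-like on chr15, Pten-like on chr19, ...), each with a few
#' exons. Coordinates are invented at mouse scale; these are fixtures, not
#' real annotations.
#'
#' @return `gene_models` object.
#' @export
default_gene_models <- function() {
  g <- data.frame(
    gene = c("Myc", "Pten", "Magi2", "Naaladl2", "Smad3", "Igf1r",
             "Duxbl1", "Yap1"),
    chrom = c("chr15", "chr19", "chr5", "chr3", "chr9", "chr7",
              "chr14", "chr9"),
    strand = c("+", "+", "-", "+", "-", "+", "+", "-"),
    start = c(61900000, 32750000, 19800000, 50300000, 63700000, 67600000,
              55400000, 7900000),
    end = c(61910000, 32820000, 21200000, 51600000, 63810000, 67910000,
            55410000, 7980000),
    stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    span <- g$end[i] - g$start[i]
    starts <- g$start[i] + round(span * c(0.00, 0.45, 0.90))
    ends <- pmin(starts + max(200, round(span * 0.05)), g$end[i])
    data.frame(gene = g$gene[i], chrom = g$chrom[i], start = starts,
               end = ends, stringsAsFactors = FALSE)
  }))
  structure(list(genes = g, exons = exons), class = "gene_models")
}

## ---- clone tree ------------------------------------------------------------

# Balanced rooted binary tree over samples S1..Sn (nested list of sample
# names) plus its branch table: one truncal root branch, one shared
# branch per non-root internal node, one private branch per leaf.
build_clone_tree <- function(sample_ids) {
  split_rec <- function(ids) {
    if (length(ids) == 1) return(ids)
    h <- ceiling(length(ids) / 2)
    list(split_rec(ids[seq_len(h)]), split_rec(ids[-seq_len(h)]))
  }
  nested <- split_rec(sample_ids)
  branches <- list()
  add <- function(samples, type) {
    branches[[length(branches) + 1]] <<- list(
      branch_id = sprintf("b%02d", length(branches) + 1L),
      type = type, samples = samples
    )
  }
  add(sample_ids, "truncal")
  walk <- function(node, is_root) {
    if (!is.list(node)) {
      add(node, "private")
      return(invisible())
    }
    if (!is_root) add(sort(unlist(node)), "shared")
    walk(node[[1]], FALSE)
    walk(node[[2]], FALSE)
  }
  if (length(sample_ids) > 1) walk(nested, TRUE)
  list(nested = nested, branches = branches)
}

## ---- CGR planting ----------------------------------------------------------

# A chain of equal-length intervals shifted by half their length: adjacent
# intervals partially overlap (interleaved), non-adjacent ones merely
# touch, so the interleaving graph is a path with one component.
interleaved_chain <- function(chrom, start, n, interval_len, types) {
  step <- interval_len / 2
  p1 <- start + (seq_len(n) - 1) * step
  p2 <- p1 + interval_len
  strands <- list(DEL = c("+", "-"), DUP = c("-", "+"),
                  h2hINV = c("+", "+"), t2tINV = c("-", "-"))
  s <- do.call(rbind, strands[types])
  sv_calls(chrom1 = chrom, pos1 = round(p1), strand1 = s[, 1],
           chrom2 = chrom, pos2 = round(p2), strand2 = s[, 2],
           svtype = types)
}

#' Plant one complex genomic rearrangement
#'
#' Emits the SVs and the copy-number profile of one CGR per its spec:
#' chromothripsis yields a single interleaved cluster with copy number
#' oscillating between two states across the footprint; bfb yields a
#' cluster containing foldback (head-to-head) inversions, escalating
#' segmental amplification and a terminal loss; multichromosomal yields
#' one cluster per chromosome plus translocations whose breakpoints fall
#' inside the linked footprints. The planted SVs on each chromosome form
#' a single connected interleaving component, which is verified before
#' returning. Consumes the R RNG stream.
#'
#' @param spec a [cgr_spec()].
#' @param genome chromosome-length table.
#' @param genes `gene_models` for amplified-gene placement.
#' @return list with `svs` (SV call table; translocations included for
#'   the multichromosomal style), `cn_pieces` (`chrom`, `start`, `end`,
#'   `copy_number` to overlay on the baseline), `footprints` (per-
#'   chromosome cluster extents) and `amplified_gene`.
#' @export
plant_cgr <- function(spec, genome, genes = default_gene_models()) {
  if (!inherits(spec, "cgr_spec")) {
    spec <- do.call(cgr_spec, spec)
  }
  missing <- setdiff(spec$chromosomes, genome$chrom)
  if (length(missing)) {
    stop("spec chromosome(s) not in genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  interval_len <- 2e6
  gene_row <- NULL
  if (!is.null(spec$amplified_gene)) {
    gene_row <- genes$genes[genes$genes$gene == spec$amplified_gene, ]
    if (!nrow(gene_row)) {
      stop("amplified_gene not in gene models: ", spec$amplified_gene,
           call. = FALSE)
    }
    if (!(gene_row$chrom %in% spec$chromosomes)) {
      stop("amplified_gene is not on a spec chromosome", call. = FALSE)
    }
  }
  n_chrom <- length(spec$chromosomes)
  per_chrom <- rep(spec$n_svs %/% n_chrom, n_chrom)
  per_chrom[seq_len(spec$n_svs %% n_chrom)] <-
    per_chrom[seq_len(spec$n_svs %% n_chrom)] + 1L
  svs <- list(); cn_pieces <- list(); footprints <- list()
  for (k in seq_len(n_chrom)) {
    ch <- spec$chromosomes[k]
    m <- per_chrom[k]
    chrom_len <- genome$length[genome$chrom == ch]
    span <- (m - 1) * interval_len / 2 + interval_len
    if (!is.null(gene_row) && gene_row$chrom == ch) {
      start <- max(1e6, round(gene_row$start - span / 2))
    } else {
      start <- round(stats::runif(1, 1e6, chrom_len - span - 2e6))
    }
    types <- switch(spec$style,
      chromothripsis = rep_len(c("DEL", "h2hINV", "DUP", "t2tINV"), m),
      bfb = rep_len(c("h2hINV", "DEL", "h2hINV", "DUP"), m),
      multichromosomal = rep_len(c("DEL", "h2hINV", "DUP", "t2tINV"), m)
    )
    chain <- interleaved_chain(ch, start, m, interval_len, types)
    comp <- interleave_components(chain)
    stopifnot(length(unique(comp)) == 1) # generation-time connectivity check
    svs[[length(svs) + 1]] <- chain
    fp <- c(start = min(chain$pos1), end = max(chain$pos2))
    footprints[[ch]] <- fp
    # copy-number overlay
    if (spec$style == "bfb") {
      # escalating amplification toward the foldback, then terminal loss
      bounds <- round(seq(fp["start"], fp["end"], length.out = 4))
      cn_pieces[[length(cn_pieces) + 1]] <- data.frame(
        chrom = ch,
        start = c(bounds[1], bounds[2], bounds[3], fp["end"]),
        end = c(bounds[2], bounds[3], fp["end"], chrom_len),
        copy_number = c(4, spec$target_copies, 3, 1),
        stringsAsFactors = FALSE
      )
    } else {
      # oscillation between two states across the footprint
      n_seg <- max(2L, 2L * (m %/% 2L))
      bounds <- round(seq(fp["start"], fp["end"], length.out = n_seg + 1))
      cn_pieces[[length(cn_pieces) + 1]] <- data.frame(
        chrom = ch, start = bounds[-length(bounds)], end = bounds[-1],
        copy_number = rep_len(c(3, 2), n_seg), stringsAsFactors = FALSE
      )
    }
  }
  cn_pieces <- do.call(rbind, cn_pieces)
  if (!is.null(gene_row)) {
    # carve an amplified window around the gene up to target_copies,
    # clipping every overlapped piece so segments stay non-overlapping
    w1 <- gene_row$start - 1e4
    w2 <- gene_row$end + 1e4
    on_chr <- cn_pieces$chrom == gene_row$chrom
    clipped <- list()
    for (i in seq_len(nrow(cn_pieces))) {
      pc <- cn_pieces[i, ]
      if (!on_chr[i] || pc$end <= w1 || pc$start >= w2) {
        clipped[[length(clipped) + 1]] <- pc
        next
      }
      if (pc$start < w1) {
        clipped[[length(clipped) + 1]] <-
          data.frame(chrom = pc$chrom, start = pc$start, end = w1,
                     copy_number = pc$copy_number, stringsAsFactors = FALSE)
      }
      if (pc$end > w2) {
        clipped[[length(clipped) + 1]] <-
          data.frame(chrom = pc$chrom, start = w2, end = pc$end,
                     copy_number = pc$copy_number, stringsAsFactors = FALSE)
      }
    }
    amp <- data.frame(chrom = gene_row$chrom, start = w1, end = w2,
                      copy_number = spec$target_copies,
                      stringsAsFactors = FALSE)
    cn_pieces <- rbind(do.call(rbind, clipped), amp)
    cn_pieces <- cn_pieces[order(cn_pieces$chrom, cn_pieces$start), ]
  }
  svs <- do.call(rbind, svs)
  if (spec$style == "multichromosomal") {
    pairs <- cbind(spec$chromosomes[-n_chrom], spec$chromosomes[-1])
    tra <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      f1 <- footprints[[pairs[i, 1]]]
      f2 <- footprints[[pairs[i, 2]]]
      mid1 <- round(mean(f1)); mid2 <- round(mean(f2))
      sv_calls(chrom1 = rep(pairs[i, 1], 3),
               pos1 = mid1 + c(-3e5, 0, 3e5), strand1 = c("+", "-", "+"),
               chrom2 = rep(pairs[i, 2], 3),
               pos2 = mid2 + c(-3e5, 0, 3e5), strand2 = c("-", "+", "+"),
               svtype = "TRA")
    }))
    svs <- rbind(svs, tra)
  }
  rownames(svs) <- NULL
  rownames(cn_pieces) <- NULL
  list(svs = svs, cn_pieces = cn_pieces, footprints = footprints,
       amplified_gene = spec$amplified_gene, style = spec$style)
}

## ---- cohort simulation -----------------------------------------------------

rand_positions <- function(n, genome) {
  if (!n) {
    return(data.frame(chrom = character(), pos = numeric(),
                      stringsAsFactors = FALSE))
  }
  ci <- sample.int(nrow(genome), n, replace = TRUE,
                   prob = genome$length / sum(genome$length))
  data.frame(chrom = genome$chrom[ci],
             pos = floor(stats::runif(n, 0, genome$length[ci])),
             stringsAsFactors = FALSE)
}

rand_bases <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Simulate a multi-region tumor cohort with known ground truth
#'
#' See [sim_config()] for the stated world. Deterministic: the same
#' config (including seed) yields an identical cohort.
#'
#' @param config a [sim_config()].
#' @return `synthetic_cohort` list: `config`, `truth` (clone tree, SNV /
#'   SV / cluster / gene truth tables, purity), `samples` (per-sample
#'   `svs`, `snvs`, `segments`), `site_table` (per-site per-sample depth
#'   and alt support for presence calling), `normals` (panel-of-normals
#'   SNV sets), `annotations` (impact table for the somatic SNVs) and
#'   `depth_table`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be created with sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  genome <- config$genome
  genes <- config$genes
  sample_ids <- sprintf("S%d", seq_len(config$n_samples))
  tree <- build_clone_tree(sample_ids)
  branches <- tree$branches
  btypes <- vapply(branches, `[[`, "", "type")

  ## --- SNVs per branch
  snv_count <- ifelse(btypes == "truncal", config$n_truncal_snvs,
                      ifelse(btypes == "shared", config$n_shared_snvs,
                             config$n_private_snvs))
  total_snvs <- sum(snv_count)
  pos <- rand_positions(total_snvs, genome)
  while (anyDuplicated(paste(pos$chrom, pos$pos))) {
    dup <- duplicated(paste(pos$chrom, pos$pos))
    pos[dup, ] <- rand_positions(sum(dup), genome)
  }
  bases <- rand_bases(total_snvs)
  snv_truth <- data.frame(
    chrom = pos$chrom, pos = pos$pos, ref = bases$ref, alt = bases$alt,
    branch_id = rep(vapply(branches, `[[`, "", "branch_id"), snv_count),
    clonality = rep(btypes, snv_count), stringsAsFactors = FALSE
  )
  snv_truth$key <- snv_key(snv_truth)

  ## --- planted CGRs (truncal)
  planted <- lapply(config$cgr_specs, plant_cgr, genome = genome,
                    genes = genes)
  cgr_svs <- list(); cluster_truth <- list(); cn_overlays <- list()
  gene_truth <- list()
  for (i in seq_along(planted)) {
    p <- planted[[i]]
    ids <- sprintf("cgr%d_sv%02d", i, seq_len(nrow(p$svs)))
    p$svs$id <- ids
    cgr_svs[[i]] <- p$svs
    cn_overlays[[i]] <- p$cn_pieces
    for (ch in names(p$footprints)) {
      member <- p$svs$chrom1 == ch & p$svs$chrom2 == ch
      cluster_truth[[length(cluster_truth) + 1]] <- data.frame(
        cgr_index = i, chrom = ch,
        start = p$footprints[[ch]]["start"], end = p$footprints[[ch]]["end"],
        n_svs = sum(member), style = p$style,
        member_ids = paste(p$svs$id[member], collapse = ","),
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(p$amplified_gene)) {
      spec <- config$cgr_specs[[i]]
      gene_truth[[length(gene_truth) + 1]] <- data.frame(
        gene = p$amplified_gene, category = "amplification",
        copies = spec$target_copies, cgr_index = i, stringsAsFactors = FALSE
      )
    }
  }
  cluster_truth <- if (length(cluster_truth)) do.call(rbind, cluster_truth)
    else data.frame(cgr_index = integer(), chrom = character(),
                    start = numeric(), end = numeric(), n_svs = integer(),
                    style = character(), member_ids = character(),
                    stringsAsFactors = FALSE)
  gene_truth <- if (length(gene_truth)) do.call(rbind, gene_truth)
    else data.frame(gene = character(), category = character(),
                    copies = numeric(), cgr_index = integer(),
                    stringsAsFactors = FALSE)

  ## --- background SVs: assigned round-robin over branches; rejection-
  ## sampled so no background interval partially overlaps any existing SV
  ## interval and no breakpoint lands inside a planted footprint (keeps
  ## planted cluster membership exact in the noise-free world).
  existing <- if (length(cgr_svs)) do.call(rbind, cgr_svs) else empty_sv_calls()
  in_footprint <- function(chrom, p) {
    any(vapply(seq_len(nrow(cluster_truth)), function(j) {
      cluster_truth$chrom[j] == chrom &&
        p >= cluster_truth$start[j] - 1e6 && p <= cluster_truth$end[j] + 1e6
    }, TRUE))
  }
  bg_types <- rep_len(c("DEL", "DUP", "h2hINV", "t2tINV", "TRA"),
                      config$n_background_svs)
  bg_list <- list()
  for (i in seq_len(config$n_background_svs)) {
    repeat {
      if (bg_types[i] == "TRA") {
        a <- rand_positions(1, genome); b <- rand_positions(1, genome)
        if (a$chrom == b$chrom) next
        if (in_footprint(a$chrom, a$pos) || in_footprint(b$chrom, b$pos)) next
        cand <- sv_calls(a$chrom, a$pos, "+", b$chrom, b$pos, "-",
                         svtype = "TRA")
        break
      }
      a <- rand_positions(1, genome)
      len <- round(exp(stats::runif(1, log(1e4), log(5e6))))
      chrom_len <- genome$length[genome$chrom == a$chrom]
      if (a$pos + len >= chrom_len) next
      if (in_footprint(a$chrom, a$pos) || in_footprint(a$chrom, a$pos + len)) next
      strands <- list(DEL = c("+", "-"), DUP = c("-", "+"),
                      h2hINV = c("+", "+"), t2tINV = c("-", "-"))[[bg_types[i]]]
      cand <- sv_calls(a$chrom, a$pos, strands[1], a$chrom, a$pos + len,
                       strands[2], svtype = bg_types[i])
      # reject partial overlap with any existing intrachromosomal SV
      prev <- rbind(existing, if (length(bg_list)) do.call(rbind, bg_list))
      prev <- prev[prev$chrom1 == a$chrom & prev$chrom1 == prev$chrom2, ,
                   drop = FALSE]
      clash <- FALSE
      for (j in seq_len(nrow(prev))) {
        if (interleaved(cand, prev[j, ])) { clash <- TRUE; break }
      }
      if (!clash) break
    }
    cand$id <- sprintf("bg_sv%03d", i)
    bg_list[[i]] <- cand
  }
  bg_svs <- if (length(bg_list)) do.call(rbind, bg_list) else empty_sv_calls()
  bg_branch <- rep_len(seq_along(branches), nrow(bg_svs))

  sv_truth <- rbind(
    if (nrow(existing)) data.frame(
      id = existing$id, branch_id = branches[[1]]$branch_id,
      clonality = "truncal",
      cgr_index = as.integer(sub("^cgr(\\d+)_.*$", "\\1", existing$id)),
      stringsAsFactors = FALSE),
    if (nrow(bg_svs)) data.frame(
      id = bg_svs$id,
      branch_id = vapply(bg_branch, function(b) branches[[b]]$branch_id, ""),
      clonality = btypes[bg_branch], cgr_index = NA_integer_,
      stringsAsFactors = FALSE)
  )
  if (is.null(sv_truth)) {
    sv_truth <- data.frame(id = character(), branch_id = character(),
                           clonality = character(), cgr_index = integer(),
                           stringsAsFactors = FALSE)
  }
  all_svs <- rbind(existing, bg_svs)
  sv_branch_samples <- c(
    rep(list(sample_ids), nrow(existing)),
    lapply(bg_branch, function(b) branches[[b]]$samples)
  )

  ## --- copy-number segments (planted CGRs are truncal: same CN in all
  ## samples; log2 ratios distorted per-sample by purity)
  overlay <- if (length(cn_overlays)) do.call(rbind, cn_overlays)
    else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    copy_number = numeric(), stringsAsFactors = FALSE)
  base_segments <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    ov <- overlay[overlay$chrom == ch, , drop = FALSE]
    ov <- ov[order(ov$start), , drop = FALSE]
    pieces <- list()
    cursor <- 0
    for (j in seq_len(nrow(ov))) {
      if (ov$start[j] > cursor) {
        pieces[[length(pieces) + 1]] <- data.frame(
          chrom = ch, start = cursor, end = ov$start[j],
          copy_number = config$ploidy, stringsAsFactors = FALSE)
      }
      pieces[[length(pieces) + 1]] <- ov[j, c("chrom", "start", "end",
                                              "copy_number")]
      cursor <- ov$end[j]
    }
    if (cursor < genome$length[i]) {
      pieces[[length(pieces) + 1]] <- data.frame(
        chrom = ch, start = cursor, end = genome$length[i],
        copy_number = config$ploidy, stringsAsFactors = FALSE)
    }
    do.call(rbind, pieces)
  }))
  rownames(base_segments) <- NULL

  ## --- germline variants and panel of normals
  gpos <- rand_positions(config$n_germline, genome)
  gbases <- rand_bases(config$n_germline)
  germline <- snv_calls(gpos$chrom, gpos$pos, gbases$ref, gbases$alt,
                        depth = 30, alt_count = 15, callers = "mutect2")
  normals <- lapply(seq_len(config$n_normals), function(i) {
    g <- germline
    g$sample_id <- sprintf("N%d", i)
    g
  })

  ## --- per-sample call sets
  jitter_pos <- function(p) {
    if (config$breakpoint_jitter > 0) {
      pmax(0, round(p + stats::rnorm(length(p), 0, config$breakpoint_jitter)))
    } else p
  }
  samples <- stats::setNames(vector("list", config$n_samples), sample_ids)
  for (si in seq_along(sample_ids)) {
    s <- sample_ids[si]
    pur <- config$purity_per_sample[si]
    carried_sv <- vapply(sv_branch_samples, function(bs) s %in% bs, TRUE)
    sv <- all_svs[carried_sv, , drop = FALSE]
    if (nrow(sv)) {
      if (config$dropout_rate > 0) {
        sv <- sv[stats::runif(nrow(sv)) >= config$dropout_rate, ,
                 drop = FALSE]
      }
      sv$pos1 <- jitter_pos(sv$pos1)
      sv$pos2 <- jitter_pos(sv$pos2)
      sv$depth <- config$depth_mean
      sv$alt_reads <- round(0.5 * pur * config$depth_mean)
      sv$vaf <- sv$alt_reads / sv$depth
      sv$sample_id <- s
    }
    carried_snv <- vapply(snv_truth$branch_id, function(b) {
      s %in% branches[[match(b, vapply(branches, `[[`, "", "branch_id"))]]$samples
    }, TRUE)
    snv <- snv_calls(
      chrom = snv_truth$chrom[carried_snv], pos = snv_truth$pos[carried_snv],
      ref = snv_truth$ref[carried_snv], alt = snv_truth$alt[carried_snv],
      depth = config$depth_mean,
      alt_count = round(0.5 * pur * config$depth_mean),
      callers = "mutect2,muse", sample_id = s
    )
    if (config$dropout_rate > 0 && nrow(snv)) {
      snv <- snv[stats::runif(nrow(snv)) >= config$dropout_rate, ,
                 drop = FALSE]
    }
    if (config$germline_leakage > 0 && nrow(germline)) {
      leak <- germline[seq_len(min(config$germline_leakage, nrow(germline))), ]
      leak$sample_id <- s
      leak$depth <- config$depth_mean
      leak$alt_count <- round(0.5 * config$depth_mean)
      leak$vaf <- leak$alt_count / leak$depth
      leak$callers <- "mutect2,muse"
      snv <- rbind(snv, leak)
    }
    seg <- base_segments
    seg$log2_fold_change <- log2fc_from_cn(seg$copy_number, pur,
                                           config$ploidy)
    seg <- seg[, c("chrom", "start", "end", "log2_fold_change",
                   "copy_number")]
    samples[[s]] <- list(svs = sv, snvs = snv, segments = seg)
  }

  ## --- presence-call site table (all somatic SNV sites x all samples)
  site_table <- do.call(rbind, lapply(seq_along(sample_ids), function(si) {
    s <- sample_ids[si]
    carried <- vapply(snv_truth$branch_id, function(b) {
      s %in% branches[[match(b, vapply(branches, `[[`, "", "branch_id"))]]$samples
    }, TRUE)
    alt <- ifelse(carried,
                  round(0.5 * config$purity_per_sample[si] *
                          config$depth_mean), 0)
    n_sites <- nrow(snv_truth)
    data.frame(key = snv_truth$key, sample_id = rep(s, n_sites),
               depth = rep(config$depth_mean, n_sites),
               hq_alt_count = as.numeric(alt),
               detected = as.logical(carried), stringsAsFactors = FALSE)
  }))

  ## --- impact annotations for the somatic SNVs
  exons <- genes$exons
  in_exon <- vapply(seq_len(nrow(snv_truth)), function(i) {
    hit <- exons$chrom == snv_truth$chrom[i] &
      snv_truth$pos[i] >= exons$start & snv_truth$pos[i] < exons$end
    if (any(hit)) exons$gene[which(hit)[1]] else NA_character_
  }, "")
  annotations <- data.frame(
    key = snv_truth$key,
    gene = ifelse(is.na(in_exon), "", in_exon),
    consequence = ifelse(is.na(in_exon), "intergenic_variant",
                         "missense_variant"),
    impact = ifelse(is.na(in_exon), "MODIFIER", "MODERATE"),
    deleterious = !is.na(in_exon), stringsAsFactors = FALSE
  )

  cohort <- structure(list(
    config = config,
    truth = list(
      tree = tree, branches = branches, snvs = snv_truth, svs = sv_truth,
      clusters = cluster_truth, genes = gene_truth,
      purity = data.frame(sample_id = sample_ids,
                          purity = config$purity_per_sample,
                          stringsAsFactors = FALSE)
    ),
    samples = samples, normals = normals, site_table = site_table,
    annotations = annotations
  ), class = "synthetic_cohort")
  cohort$depth_table <- emit_depth_table(cohort)
  cohort
}

#' Simulated coverage-depth summary at the engineered deletion locus
#'
#' Every tumor cell carries a biallelic deletion of the edit region, so
#' its expected depth is `depth_mean * (1 - purity)`; the flanking region
#' (the broader window minus the edit site) stays at `depth_mean`. Depths
#' are Poisson-sampled at base resolution and averaged, so the estimate
#' carries realistic counting noise. Consumes the R RNG stream.
#'
#' @param cohort a `synthetic_cohort`, or `NULL` when `purity` and
#'   `depth_mean` are given directly.
#' @param purity,depth_mean,sample_ids direct-use parameters (purities may
#'   include 0 here to emulate a normal sample).
#' @param edit_region,flank_region `c(start, end)` of the edit site and
#'   the broader window on the engineered chromosome.
#' @return `data.frame` with `sample_id`, `region` (`edit` / `flank`),
#'   `mean_depth`.
#' @export
emit_depth_table <- function(cohort = NULL, purity = NULL, depth_mean = NULL,
                             sample_ids = NULL,
                             edit_region = c(69474029, 69481865),
                             flank_region = c(69400000, 69500000)) {
  if (!is.null(cohort)) {
    purity <- cohort$config$purity_per_sample
    depth_mean <- cohort$config$depth_mean
    sample_ids <- names(cohort$samples)
  }
  if (any(purity < 0 | purity > 1)) {
    stop("purity must be in [0, 1]", call. = FALSE)
  }
  l_edit <- edit_region[2] - edit_region[1]
  l_flank <- (flank_region[2] - flank_region[1]) - l_edit
  if (l_edit <= 0 || l_flank <= 0) {
    stop("edit region must be non-empty and nested in the flank window",
         call. = FALSE)
  }
  do.call(rbind, lapply(seq_along(sample_ids), function(i) {
    lam_edit <- depth_mean * (1 - purity[i])
    de <- stats::rpois(1, lam_edit * l_edit) / l_edit
    df <- stats::rpois(1, depth_mean * l_flank) / l_flank
    data.frame(sample_id = rep(sample_ids[i], 2),
               region = c("edit", "flank"), mean_depth = c(de, df),
               length = c(l_edit, l_flank), stringsAsFactors = FALSE)
  }))
}

#' Write a synthetic cohort to disk
#'
#' Emits per-sample SV VCF, SNV VCF and segment files, the
#' panel-of-normals SNV VCFs, site table, depth table, impact annotations,
#' gene models (BED12), truth tables and a cohort manifest, all as plain
#' text. Output is byte-identical for identical cohorts.
#'
#' @param cohort a `synthetic_cohort`.
#' @param outdir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  manifest <- list()
  for (s in names(cohort$samples)) {
    smp <- cohort$samples[[s]]
    write_sv_vcf(smp$svs, p(paste0(s, ".sv.vcf")), sample_name = s)
    write_snv_vcf(smp$snvs, p(paste0(s, ".snv.vcf")), sample_name = s)
    seg <- smp$segments
    seg$copy_number <- NULL # emitted files carry relative log2 only
    write_segments(seg, p(paste0(s, ".cns")))
    manifest[[s]] <- data.frame(
      sample_id = s, mouse_id = "mouse1",
      site = if (s == names(cohort$samples)[1]) "primary" else "metastasis",
      genotype = "Trp53fl/fl;Rb1fl/fl",
      sv_vcf = paste0(s, ".sv.vcf"), snv_vcf = paste0(s, ".snv.vcf"),
      segments = paste0(s, ".cns"), matched_normal = "tumor-only",
      is_primary = s == names(cohort$samples)[1], stringsAsFactors = FALSE
    )
  }
  for (i in seq_along(cohort$normals)) {
    write_snv_vcf(cohort$normals[[i]], p(sprintf("normal_%02d.snv.vcf", i)),
                  sample_name = sprintf("N%d", i))
  }
  wt <- function(df, name) {
    utils::write.table(df, p(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(cohort$site_table, "site_table.tsv")
  wt(cohort$depth_table, "depth_table.tsv")
  wt(cohort$annotations, "impact_table.tsv")
  wt(cohort$truth$snvs, "truth_snvs.tsv")
  wt(cohort$truth$svs, "truth_svs.tsv")
  wt(cohort$truth$clusters, "truth_clusters.tsv")
  wt(cohort$truth$genes, "truth_genes.tsv")
  wt(cohort$truth$purity, "truth_purity.tsv")
  write_gene_models(cohort$config$genes, p("gene_models.bed12"))
  manifest <- do.call(rbind, manifest)
  wt(manifest, "manifest.tsv")
  invisible(p("manifest.tsv"))
}
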
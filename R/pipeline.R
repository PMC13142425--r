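## End-to-end orchestration over a cohort manifest: purity -> copy number
## -> CGR detection and linkage -> gene alterations -> phylogeny (per
## multi-region mouse) -> cohort statistics. Stages are pure functions of
## their declared inputs plus the config, so a rerun on the same inputs
## is bit-identical for the deterministic stages; per-stage in/out counts
## are logged so "N of M" filter summaries are recoverable.

#' Read a cohort manifest
#'
#' Tab-separated, one row per sample: `sample_id`, `mouse_id`, `site`
#' (`primary`/`metastasis`), `genotype`, `sv_vcf`, `snv_vcf`, `segments`,
#' `matched_normal` (a control id or `"tumor-only"`), `is_primary`
#' (exactly one per mouse). Relative paths resolve against the manifest
#' directory and are checked for existence.
#'
#' @param path manifest file path.
#' @return validated manifest `data.frame` with absolute file paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "mouse_id", "site", "sv_vcf", "snv_vcf",
            "segments", "is_primary")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  man$is_primary <- as.logical(man$is_primary)
  base <- dirname(normalizePath(path))
  for (col in c("sv_vcf", "snv_vcf", "segments")) {
    rel <- !grepl("^/", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
    gone <- !file.exists(man[[col]])
    if (any(gone)) {
      stop("manifest file not found: ", man[[col]][gone][1], call. = FALSE)
    }
  }
  for (m in unique(man$mouse_id)) {
    if (sum(man$is_primary[man$mouse_id == m]) != 1) {
      stop("mouse ", m, " must have exactly one designated primary sample",
           call. = FALSE)
    }
  }
  man
}

#' Run the full analysis pipeline on a cohort directory
#'
#' @param manifest manifest `data.frame` (from [read_manifest()]) or a
#'   manifest file path.
#' @param outdir output directory for the report bundle; `NULL` for an
#'   in-memory report only.
#' @param config list of overrides: `ploidy`, `min_cluster_svs`,
#'   `link_alpha`, `cn_thresholds`, `gene_models` (path to BED12 or a
#'   `gene_models` object), `impact_table` (path or `data.frame`),
#'   `depth_table` (path or `data.frame`), `site_table` (path or
#'   `data.frame`), `blacklist` (path or intervals).
#' @return report list: `purity`, per-sample `cgr` results, `segments`
#'   with absolute copy number, `gene_calls`, `burden`, `phylogeny` per
#'   multi-region mouse, and a `log` of per-stage counts.
#' @export
run_pipeline <- function(manifest, outdir = NULL, config = list()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  cfg <- utils::modifyList(list(
    ploidy = 2, min_cluster_svs = 4, link_alpha = 0.01,
    cn_thresholds = cn_thresholds(), gene_models = NULL,
    impact_table = NULL, depth_table = NULL, site_table = NULL,
    blacklist = NULL
  ), config)
  load_tab <- function(x) {
    if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE) else x
  }
  models <- cfg$gene_models
  if (is.character(models)) models <- read_gene_models(models)
  impact <- load_tab(cfg$impact_table)
  blacklist <- if (is.character(cfg$blacklist)) read_bed(cfg$blacklist)
               else cfg$blacklist
  log <- list()
  note <- function(stage, sample, n_in, n_out) {
    log[[length(log) + 1]] <<- data.frame(
      stage = stage, sample_id = sample, n_in = n_in, n_out = n_out,
      stringsAsFactors = FALSE)
  }

  ## purity
  purity <- NULL
  if (!is.null(cfg$depth_table)) {
    purity <- purity_from_depth_table(load_tab(cfg$depth_table))
  }
  get_purity <- function(s) {
    if (is.null(purity)) return(1)
    p <- purity$purity[purity$sample_id == s]
    if (length(p)) p else 1
  }

  per_sample <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$sample_id[i]
    res <- tryCatch({
      svs <- read_sv_vcf(manifest$sv_vcf[i], sample_id = s)
      snvs <- read_snv_vcf(manifest$snv_vcf[i], sample_id = s)
      seg <- read_segments(manifest$segments[i])
      n0 <- nrow(seg)
      if (!is.null(blacklist)) seg <- filter_blacklist(seg, blacklist)
      note("blacklist_filter", s, n0, nrow(seg))
      seg$copy_number <- absolute_cn(seg$log2_fold_change, get_purity(s),
                                     cfg$ploidy)
      seg$state <- classify_cn_state(seg$copy_number, cfg$cn_thresholds)
      clusters <- detect_clusters(svs, min_svs = cfg$min_cluster_svs)
      links <- link_multichromosomal(clusters, svs, alpha = cfg$link_alpha)
      note("cgr_detect", s, nrow(svs), nrow(clusters$clusters))
      gene_calls <- NULL
      if (!is.null(models)) {
        calls <- list()
        for (g in models$genes$gene) {
          gcn <- suppressWarnings(gene_weighted_cn(g, models, seg))
          ccn <- chromosome_average_cn(
            models$genes$chrom[models$genes$gene == g], seg)
          calls[[length(calls) + 1]] <- call_gene_cn(g, gcn, ccn,
                                                     sample_id = s)
          calls[[length(calls) + 1]] <- call_sv_disruption(g, models, svs,
                                                           sample_id = s)
        }
        if (!is.null(impact)) {
          sm <- call_small_variants(snvs, impact, sample_id = s)
          calls[[length(calls) + 1]] <- sm$calls
        }
        gene_calls <- do.call(rbind, calls)
        if (!is.null(gene_calls) && nrow(gene_calls)) {
          gene_calls <- flag_cgr_cooccurrence(gene_calls, models, clusters)
        }
      }
      burden <- data.frame(
        sample_id = s, sv_breakpoints = sv_burden(svs),
        fraction_in_cgr = breakpoint_fraction_in_cgr(svs, clusters),
        tmb = if (!is.null(impact) && !is.null(models))
          tmb(snvs, impact, coding_territory_mb(models)) else NA_real_,
        stringsAsFactors = FALSE
      )
      list(svs = svs, snvs = snvs, segments = seg, clusters = clusters,
           links = links, gene_calls = gene_calls, burden = burden)
    }, error = function(e) {
      stop(sprintf("pipeline stage failed for sample %s: %s", s,
                   conditionMessage(e)), call. = FALSE)
    })
    per_sample[[s]] <- res
  }

  ## phylogeny per multi-region mouse
  phylo <- list()
  site_table <- load_tab(cfg$site_table)
  for (m in unique(manifest$mouse_id)) {
    ids <- manifest$sample_id[manifest$mouse_id == m]
    if (length(ids) < 2 || is.null(site_table)) next
    st <- site_table[site_table$sample_id %in% ids, , drop = FALSE]
    pm <- build_presence_matrix(st)
    if (!nrow(pm)) next
    fit <- search_parsimony_tree(pm)
    lens <- assign_branch_lengths(fit$tree, pm)
    phylo[[m]] <- list(matrix = pm, tree = lens$tree, score = fit$score,
                       unassigned = lens$unassigned,
                       clonality = attr(pm, "clonality"))
  }

  burden <- do.call(rbind, lapply(per_sample, `[[`, "burden"))
  rownames(burden) <- NULL
  report <- list(manifest = manifest, purity = purity,
                 samples = per_sample, burden = burden, phylogeny = phylo,
                 log = do.call(rbind, log))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(burden, file.path(outdir, "burden.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(purity)) {
      utils::write.table(purity, file.path(outdir, "purity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    all_clusters <- do.call(rbind, lapply(names(per_sample), function(s) {
      cl <- per_sample[[s]]$clusters$clusters
      if (nrow(cl)) cbind(sample_id = s, cl) else NULL
    }))
    if (!is.null(all_clusters)) {
      utils::write.table(all_clusters, file.path(outdir, "cgr_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    all_calls <- do.call(rbind, lapply(per_sample, `[[`, "gene_calls"))
    if (!is.null(all_calls) && nrow(all_calls)) {
      utils::write.table(all_calls, file.path(outdir, "gene_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (m in names(phylo)) {
      tr <- phylo[[m]]$tree
      ape::write.tree(tr, file.path(outdir, paste0("phylogeny_", m, ".nwk")))
    }
    meta <- list(
      package = "cgrscope",
      version = as.character(utils::packageVersion("cgrscope")),
      config = cfg[c("ploidy", "min_cluster_svs", "link_alpha")],
      n_samples = nrow(manifest)
    )
    jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort) and `run` (run the
#' pipeline on a manifest). Used by the `inst/cli/cgrscope` script.
#'
#' @param args character vector of arguments (default: command line).
#' @return exit status, invisibly.
#' @export
cgrscope_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cgrscope <command> [options]",
    "  simulate --outdir DIR [--seed N] [--samples N]",
    "  run --manifest FILE --outdir DIR [--seed N]",
    sep = "\n")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i) || i == length(args)) default else args[i + 1]
  }
  if (cmd == "simulate") {
    outdir <- opt("--outdir")
    if (is.null(outdir)) { message(usage); return(invisible(1L)) }
    seed <- as.integer(opt("--seed", "1"))
    n <- as.integer(opt("--samples", "4"))
    cohort <- simulate_cohort(sim_config(n_samples = n, seed = seed))
    write_cohort(cohort, outdir)
    message("cohort written to ", outdir)
    return(invisible(0L))
  }
  if (cmd == "run") {
    manifest <- opt("--manifest")
    outdir <- opt("--outdir")
    if (is.null(manifest) || is.null(outdir)) {
      message(usage)
      return(invisible(1L))
    }
    base <- dirname(normalizePath(manifest))
    maybe <- function(name) {
      f <- file.path(base, name)
      if (file.exists(f)) f else NULL
    }
    run_pipeline(manifest, outdir = outdir, config = list(
      gene_models = maybe("gene_models.bed12"),
      impact_table = maybe("impact_table.tsv"),
      depth_table = maybe("depth_table.tsv"),
      site_table = maybe("site_table.tsv")
    ))
    message("report written to ", outdir)
    return(invisible(0L))
  }
  message("unknown command: ", cmd, "\n", usage)
  invisible(1L)
}
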
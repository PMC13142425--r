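## Tumor purity from coverage at an engineered biallelic-deletion locus.
##
## In the engineered model every Cre-recombined tumor cell has lost both
## copies of the floxed edit site, so coverage there comes only from
## admixed normal cells. With mean depth d_e over the edit site and d_f
## over a flanking region of normal copy number, the tumor cell fraction
## is 1 - d_e/d_f. This biallelic-deletion model is an assumption of the
## estimator and is recorded in the output.

#' Estimate tumor purity from edit-site vs flank coverage
#'
#' @param depth_edit mean coverage depth over the engineered deletion.
#' @param depth_flank mean coverage depth over the flanking region
#'   (excluding the edit site); must be positive.
#' @param sample_id optional label.
#' @return `data.frame` (one row) with `sample_id`, `depth_edit`,
#'   `depth_flank`, `purity` (clamped to \[0, 1\]) and a logical `qc_flag`
#'   set when the depth ratio is within noise of 1 (purity indistinguishable
#'   from 0).
#' @export
#' @examples
#' estimate_purity(25, 100)$purity # 0.75
estimate_purity <- function(depth_edit, depth_flank, sample_id = NA_character_) {
  if (any(depth_flank <= 0)) {
    stop("depth_flank must be > 0", call. = FALSE)
  }
  if (any(depth_edit < 0)) {
    stop("depth_edit must be >= 0", call. = FALSE)
  }
  ratio <- depth_edit / depth_flank
  if (any(ratio > 1)) {
    warning("edit-site depth exceeds flank depth; purity clamped to 0")
  }
  purity <- pmin(pmax(1 - ratio, 0), 1)
  # flag estimates indistinguishable from 0 at Poisson noise scale
  qc <- abs(ratio - 1) <= 3 / sqrt(pmax(depth_flank, 1))
  data.frame(sample_id = sample_id, depth_edit = depth_edit,
             depth_flank = depth_flank, purity = purity, qc_flag = qc,
             model = "biallelic_deletion", stringsAsFactors = FALSE)
}

#' Estimate purity for every sample in a depth summary table
#'
#' @param depth_table `data.frame` with columns `sample_id`, `region`
#'   (values `"edit"` and `"flank"`) and `mean_depth`, as produced by
#'   [emit_depth_table()].
#' @return one [estimate_purity()] row per sample.
#' @export
purity_from_depth_table <- function(depth_table) {
  need <- c("sample_id", "region", "mean_depth")
  if (!all(need %in% names(depth_table))) {
    stop("depth table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  samples <- unique(depth_table$sample_id)
  do.call(rbind, lapply(samples, function(s) {
    d <- depth_table[depth_table$sample_id == s, ]
    de <- d$mean_depth[d$region == "edit"]
    df <- d$mean_depth[d$region == "flank"]
    if (length(de) != 1 || length(df) != 1) {
      stop("sample ", s, " must have exactly one edit and one flank row",
           call. = FALSE)
    }
    estimate_purity(de, df, sample_id = s)
  }))
}
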
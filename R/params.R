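#' Analysis parameters
#'
#' Bundles every threshold and window used across the pipeline. Defaults are
#' the published values: read-through contrasts the first 1 kb downstream of
#' the TES against the gene body (with the 500 bp pre-TES window reported
#' alongside), genes with a neighbour within 5 kb of their promoter are
#' excluded, genes with control TPM < 5 are excluded, upstream read-through
#' contamination is assessed over 1 kb preceding the TSS, PROMPTs are classed
#' upregulated at log2FC >= 1, differential calls require >= 2-fold change at
#' FDR <= 0.05, and proximity-labelling candidates require a mean abundance
#' ratio < 0.70 with >= 5 peptides.
#'
#' @param post_tes_window bp downstream of the TES scored for read-through.
#' @param pre_tes_window bp immediately upstream of the TES (alternative
#'   read-through denominator).
#' @param neighbour_distance bp; genes with another gene's span within this
#'   distance of their TSS are excluded from metagene/PROMPT cohorts.
#' @param tpm_min minimum control-condition TPM for a gene to count as
#'   expressed (genes with TPM < tpm_min are flagged; TPM = tpm_min is kept).
#' @param upstream_filter_window bp upstream of the TSS scored for
#'   read-through contamination from an upstream gene.
#' @param prompt_window bp; length of the antisense window upstream of the
#'   TSS used to quantify PROMPTs.
#' @param log2fc_up_threshold log2 fold-change at or above which a PROMPT (or
#'   upstream window) is classed upregulated (inclusive).
#' @param fold_up_threshold linear fold-change gate for differential calls.
#' @param fdr_threshold BH-adjusted p-value gate for differential calls.
#' @param ratio_threshold proteins with mean abundance ratio strictly below
#'   this are candidate depleted interactors.
#' @param min_peptides proteins with fewer peptides are discarded (strict:
#'   peptide_count >= min_peptides is kept).
#' @param pseudocount added to numerator and denominator of every log2
#'   coverage ratio, in (post-normalisation) coverage units.
#' @return An object of class \code{analysis_params} (a validated list).
#' @export
analysis_params <- function(post_tes_window = 1000L,
                            pre_tes_window = 500L,
                            neighbour_distance = 5000L,
                            tpm_min = 5,
                            upstream_filter_window = 1000L,
                            prompt_window = 3000L,
                            log2fc_up_threshold = 1.0,
                            fold_up_threshold = 2.0,
                            fdr_threshold = 0.05,
                            ratio_threshold = 0.70,
                            min_peptides = 5L,
                            pseudocount = 0.01) {
  p <- list(
    post_tes_window = as.integer(post_tes_window),
    pre_tes_window = as.integer(pre_tes_window),
    neighbour_distance = as.integer(neighbour_distance),
    tpm_min = as.numeric(tpm_min),
    upstream_filter_window = as.integer(upstream_filter_window),
    prompt_window = as.integer(prompt_window),
    log2fc_up_threshold = as.numeric(log2fc_up_threshold),
    fold_up_threshold = as.numeric(fold_up_threshold),
    fdr_threshold = as.numeric(fdr_threshold),
    ratio_threshold = as.numeric(ratio_threshold),
    min_peptides = as.integer(min_peptides),
    pseudocount = as.numeric(pseudocount)
  )
  windows <- c("post_tes_window", "pre_tes_window", "neighbour_distance",
               "upstream_filter_window", "prompt_window")
  for (w in windows) {
    if (is.na(p[[w]]) || p[[w]] <= 0L) stop(w, " must be > 0")
  }
  thresholds <- c("tpm_min", "log2fc_up_threshold", "fold_up_threshold",
                  "fdr_threshold", "ratio_threshold", "pseudocount")
  for (t in thresholds) {
    if (is.na(p[[t]]) || p[[t]] <= 0) stop(t, " must be > 0")
  }
  if (p$min_peptides < 0L) stop("min_peptides must be >= 0")
  structure(p, class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("analysis_params:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
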
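#' Load a proximity-labelling quantification table
#'
#' Expects a TSV with columns \code{protein_id}, \code{peptide_count} and at
#' least one per-replicate abundance-ratio column (named \code{ratio*},
#' depleted/control). The mean ratio is taken over the observed (non-NA)
#' replicate ratios; the number observed is recorded so downstream filtering
#' can require a minimum. Contaminants (e.g. keratins, promiscuously
#' biotinylated proteins) are flagged by exact identifier membership in
#' \code{contaminants}.
#'
#' @param path TSV path.
#' @param contaminants character vector of identifiers (or path to a
#'   one-identifier-per-line file).
#' @return data.frame: protein_id, peptide_count, ratio columns, n_ratios,
#'   mean_ratio, contaminant.
#' @export
load_quant_table <- function(path, contaminants = character()) {
  if (length(contaminants) == 1 && file.exists(contaminants)) {
    contaminants <- readLines(contaminants)
    contaminants <- contaminants[nzchar(trimws(contaminants))]
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("protein_id", "peptide_count")
  if (!all(req %in% names(tab))) {
    stop("quant table needs columns: ", paste(req, collapse = ", "))
  }
  ratio_cols <- grep("^ratio", names(tab), value = TRUE)
  if (!length(ratio_cols)) stop("quant table has no ratio columns")
  rm_mat <- as.matrix(tab[, ratio_cols, drop = FALSE])
  if (any(rm_mat < 0, na.rm = TRUE)) stop("negative abundance ratio")
  tab$n_ratios <- rowSums(!is.na(rm_mat))
  tab$mean_ratio <- rowMeans(rm_mat, na.rm = TRUE)
  tab$mean_ratio[tab$n_ratios == 0] <- NA_real_
  tab$contaminant <- tab$protein_id %in% contaminants
  tab
}

#' Select candidate depleted interactors
#'
#' A protein is a candidate iff it is not a contaminant, carries at least
#' \code{min_peptides} peptides (proteins with fewer are discarded), has at
#' least \code{min_observed} observed replicate ratios, and its mean
#' abundance ratio is strictly below \code{ratio_threshold} (a ratio of
#' exactly 0.70 is excluded). Candidates are returned sorted by ascending
#' mean ratio (largest decrease first), ties broken by protein_id.
#'
#' @param quants output of [load_quant_table()].
#' @param params [analysis_params()].
#' @param min_observed minimum non-NA replicate ratios (default 2).
#' @param all return the full annotated table (with a \code{candidate}
#'   column) instead of candidates only.
#' @return data.frame of candidates (or full table when \code{all = TRUE}).
#' @export
filter_candidates <- function(quants, params = analysis_params(),
                              min_observed = 2L, all = FALSE) {
  cand <- !quants$contaminant &
    quants$peptide_count >= params$min_peptides &
    quants$n_ratios >= min_observed &
    !is.na(quants$mean_ratio) &
    quants$mean_ratio < params$ratio_threshold
  quants$candidate <- cand
  if (all) {
    return(quants[order(quants$mean_ratio, quants$protein_id), ,
                  drop = FALSE])
  }
  out <- quants[cand, , drop = FALSE]
  out <- out[order(out$mean_ratio, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
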
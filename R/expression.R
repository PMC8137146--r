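#' Count reads overlapping a gene's exons
#'
#' A read counts iff it is on the gene's strand and overlaps at least one
#' base of at least one exon; a read touching several exons of the same gene
#' counts once.
#'
#' @param reads stranded interval table.
#' @param gene single-row gene models entry (or a one-row subset).
#' @return non-negative integer.
#' @export
count_exonic <- function(reads, gene) {
  sel <- reads$chrom == gene$chrom[1] & reads$strand == gene$strand[1]
  if (!any(sel)) return(0L)
  ex <- gene$exons[[1]]
  rir <- IRanges::IRanges(start = reads$start[sel] + 1L, end = reads$end[sel])
  eir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  sum(IRanges::overlapsAny(rir, eir))
}

#' Exonic counts for a set of genes
#' @param reads stranded interval table.
#' @param genes gene models.
#' @return integer vector named by gene_id.
#' @export
count_exonic_all <- function(reads, genes) {
  stats::setNames(vapply(seq_len(nrow(genes)), function(i) {
    count_exonic(reads, genes[i, , drop = FALSE])
  }, 0L), genes$gene_id)
}

#' Transcripts per million
#'
#' \code{rate_g = count_g / (length_g / 1000)};
#' \code{tpm_g = rate_g * 1e6 / sum(rates)}. All-zero counts give all-zero
#' TPM rather than a division error.
#'
#' @param counts non-negative per-gene counts.
#' @param exonic_lengths per-gene exonic lengths (bp, >= 1).
#' @return per-gene TPM (sums to 1e6 when any count > 0).
#' @export
compute_tpm <- function(counts, exonic_lengths) {
  if (length(counts) != length(exonic_lengths)) {
    stop("counts and exonic_lengths must have equal length")
  }
  if (any(exonic_lengths < 1)) stop("exonic lengths must be >= 1")
  rates <- counts / (exonic_lengths / 1000)
  s <- sum(rates)
  if (s == 0) return(rates)
  rates * 1e6 / s
}

#' Flag low-expression genes (control TPM below threshold)
#'
#' Genes with control TPM strictly below \code{tpm_min} (default 5) are
#' flagged \code{low_expression}; TPM equal to the threshold is retained.
#'
#' @param expr data.frame with columns \code{gene_id} and \code{tpm}
#'   (control-condition TPM).
#' @param params [analysis_params()].
#' @return \code{expr} with a logical \code{low_expression} column added;
#'   the retained subset is \code{expr[!expr$low_expression, ]}.
#' @export
filter_expressed <- function(expr, params = analysis_params()) {
  expr$low_expression <- expr$tpm < params$tpm_min
  expr
}

#' Flag genes contaminated by read-through from an upstream gene
#'
#' For each gene the sense-strand mean over the window
#' \code{[TSS - w, TSS)} (transcription orientation; \code{w =
#' upstream_filter_window}) is computed in both conditions and the gene is
#' flagged when \code{log2((m_cond + p) / (m_ctrl + p)) >=
#' log2fc_up_threshold}. Genes whose window lies entirely off-chromosome are
#' skipped with a warning (NA flag).
#'
#' @param genes gene models.
#' @param cov_control,cov_condition \code{stranded_coverage} tracks sharing
#'   normalisation.
#' @param params [analysis_params()].
#' @return data.frame: gene_id, upstream_mean_ctrl, upstream_mean_cond,
#'   log2fc, contaminated.
#' @export
upstream_readthrough_filter <- function(genes, cov_control, cov_condition,
                                        params = analysis_params()) {
  if (cov_control$normalisation != cov_condition$normalisation) {
    stop("tracks must share normalisation")
  }
  w <- params$upstream_filter_window
  p <- params$pseudocount
  t <- tss(genes)
  n <- nrow(genes)
  m_ctrl <- m_cond <- rep(NA_real_, n)
  skipped <- character()
  for (i in seq_len(n)) {
    if (genes$strand[i] == "+") {
      st <- t[i] - w; en <- t[i]
    } else {
      st <- t[i]; en <- t[i] + w
    }
    len <- cov_control$chrom_lengths[[genes$chrom[i]]]
    if (min(en, len) <= max(st, 0)) {
      skipped <- c(skipped, genes$gene_id[i])
      next
    }
    reg <- list(chrom = genes$chrom[i], start = st, end = en,
                strand = genes$strand[i])
    m_ctrl[i] <- region_mean(cov_control, reg, "sense")
    m_cond[i] <- region_mean(cov_condition, reg, "sense")
  }
  if (length(skipped)) {
    warning("upstream window off-chromosome for: ",
            paste(skipped, collapse = ", "))
  }
  lfc <- log2((m_cond + p) / (m_ctrl + p))
  data.frame(gene_id = genes$gene_id,
             upstream_mean_ctrl = m_ctrl,
             upstream_mean_cond = m_cond,
             log2fc = lfc,
             contaminated = lfc >= params$log2fc_up_threshold,
             stringsAsFactors = FALSE)
}

# DESeq-style median-of-ratios size factors over a combined counts matrix
.size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- rowMeans(lg)
  use <- is.finite(geo)
  if (!any(use)) return(rep(1, ncol(counts)))
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - geo[use], na.rm = TRUE))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' Two-condition upregulation caller
#'
#' A deliberately simple stand-in for a full negative-binomial differential
#' expression model: library sizes are normalised by median-of-ratios size
#' factors; the per-gene two-sided test is an exact Poisson ratio test when
#' each condition has a single replicate, or a normal approximation on log2
#' normalised counts (Welch-type standard error, pseudocount 0.5) with two
#' or more replicates per condition; p-values are Benjamini-Hochberg
#' corrected. With very few replicates the normal reference is
#' anti-conservative at the extreme tail, which the fold-change gate
#' absorbs; it is not a substitute for a dispersion-modelling
#' negative-binomial framework on real data. A gene is called
#' upregulated iff its fold change is at least \code{fold_up_threshold}
#' (default 2) and its FDR at most \code{fdr_threshold} (default 0.05).
#'
#' @param counts_ctrl,counts_cond matrices (genes x replicates) of raw
#'   counts, same genes in the same order; vectors are treated as one
#'   replicate. Row names, if present, become gene_ids.
#' @param params [analysis_params()].
#' @return data.frame: gene_id, base_mean, log2fc, pvalue, fdr, upregulated.
#' @export
call_upregulated <- function(counts_ctrl, counts_cond,
                             params = analysis_params()) {
  if (is.vector(counts_ctrl)) counts_ctrl <- cbind(counts_ctrl)
  if (is.vector(counts_cond)) counts_cond <- cbind(counts_cond)
  if (ncol(counts_ctrl) < 1 || ncol(counts_cond) < 1) {
    stop("each condition needs at least one replicate")
  }
  if (nrow(counts_ctrl) != nrow(counts_cond)) {
    stop("conditions must cover the same genes")
  }
  n <- nrow(counts_ctrl)
  gid <- rownames(counts_ctrl)
  if (is.null(gid)) gid <- sprintf("gene_%05d", seq_len(n))
  combined <- cbind(counts_ctrl, counts_cond)
  sf <- .size_factors(combined)
  sf_ctrl <- sf[seq_len(ncol(counts_ctrl))]
  sf_cond <- sf[-seq_len(ncol(counts_ctrl))]
  norm_ctrl <- sweep(counts_ctrl, 2, sf_ctrl, "/")
  norm_cond <- sweep(counts_cond, 2, sf_cond, "/")
  mean_ctrl <- rowMeans(norm_ctrl)
  mean_cond <- rowMeans(norm_cond)
  pc <- 0.5
  lfc <- log2((mean_cond + pc) / (mean_ctrl + pc))
  if (ncol(counts_ctrl) >= 2 && ncol(counts_cond) >= 2) {
    # normal approximation on log2 normalised counts (Welch-type SE)
    x <- log2(norm_cond + pc)
    y <- log2(norm_ctrl + pc)
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (nx - 1)
    vy <- rowSums((y - my)^2) / (ny - 1)
    zstat <- (mx - my) / sqrt(vx / nx + vy / ny)
    pval <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
    pval[!is.finite(zstat)] <- 1
  } else {
    x <- rowSums(counts_cond)
    y <- rowSums(counts_ctrl)
    tx <- sum(sf_cond)
    ty <- sum(sf_ctrl)
    pval <- vapply(seq_len(n), function(i) {
      if (x[i] + y[i] == 0) return(1)
      stats::poisson.test(c(x[i], y[i]), T = c(tx, ty))$p.value
    }, 0)
  }
  fdr <- stats::p.adjust(pval, method = "BH")
  data.frame(gene_id = gid,
             base_mean = (mean_ctrl + mean_cond) / 2,
             log2fc = lfc,
             pvalue = pval,
             fdr = fdr,
             upregulated = (2^lfc >= params$fold_up_threshold) &
               (fdr <= params$fdr_threshold),
             stringsAsFactors = FALSE)
}
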
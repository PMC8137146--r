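#' Read-through record for one gene
#'
#' Computes sense-strand means over the gene body, the 500 bp window
#' directly preceding the TES (the PAS-proximal window) and the first 1 kb
#' downstream of the TES, all oriented by transcription direction, and a
#' read-through index
#' \deqn{rt = (post_{TES} + p) / (denom + p)}
#' where the denominator is the gene-body mean by default (the figure-level
#' normalisation) or the pre-TES mean (\code{denominator = "pre_tes"}), and
#' \code{p} is the pseudocount. On an all-zero track the index is exactly 1.
#'
#' @param cov \code{stranded_coverage}.
#' @param gene one-row gene models subset.
#' @param params [analysis_params()].
#' @param denominator \code{"body"} or \code{"pre_tes"}.
#' @param condition label stored on the record.
#' @return list of class \code{readthrough_record}, or \code{NULL} (with a
#'   warning) when the gene body is shorter than the pre-TES window.
#' @export
readthrough_record <- function(cov, gene, params = analysis_params(),
                               denominator = c("body", "pre_tes"),
                               condition = "unspecified") {
  denominator <- match.arg(denominator)
  L <- gene$end[1] - gene$start[1]
  if (L < params$pre_tes_window) {
    warning("gene ", gene$gene_id[1], " shorter than pre_tes_window; skipped")
    return(NULL)
  }
  t_end <- tes(gene)[[1]]
  if (gene$strand[1] == "+") {
    pre <- c(t_end - params$pre_tes_window, t_end)
    post <- c(t_end, t_end + params$post_tes_window)
  } else {
    pre <- c(t_end, t_end + params$pre_tes_window)
    post <- c(t_end - params$post_tes_window, t_end)
  }
  chrom_len <- cov$chrom_lengths[[gene$chrom[1]]]
  if (min(post[2], chrom_len) <= max(post[1], 0)) {
    warning("gene ", gene$gene_id[1],
            ": post-TES window entirely off-chromosome; skipped")
    return(NULL)
  }
  reg <- function(w) list(chrom = gene$chrom[1], start = w[1], end = w[2],
                          strand = gene$strand[1])
  body_mean <- region_mean(cov, reg(c(gene$start[1], gene$end[1])), "sense")
  pre_mean <- region_mean(cov, reg(pre), "sense")
  post_mean <- region_mean(cov, reg(post), "sense")
  p <- params$pseudocount
  den <- if (denominator == "body") body_mean else pre_mean
  structure(list(gene_id = gene$gene_id[1],
                 condition = condition,
                 body_mean = body_mean,
                 pre_tes_mean = pre_mean,
                 post_tes_mean = post_mean,
                 denominator = denominator,
                 rt_index = (post_mean + p) / (den + p)),
            class = "readthrough_record")
}

#' Log2 change in read-through index between conditions
#'
#' \code{log2(dep$rt_index / ctrl$rt_index)}; positive values mean increased
#' read-through on depletion.
#'
#' @param ctrl,dep \code{readthrough_record}s for the same gene, computed
#'   with the same denominator.
#' @return scalar.
#' @export
readthrough_delta <- function(ctrl, dep) {
  if (!identical(ctrl$gene_id, dep$gene_id)) {
    stop("records are for different genes: ", ctrl$gene_id, " vs ",
         dep$gene_id)
  }
  if (!identical(ctrl$denominator, dep$denominator)) {
    stop("records use different denominators")
  }
  log2(dep$rt_index / ctrl$rt_index)
}

#' Read-through table over a gene cohort
#'
#' Applies the cohort filters (neighbour exclusion; optionally the
#' low-expression filter when control TPM values are supplied), computes a
#' read-through record per gene and condition, and returns one row per gene
#' sorted by decreasing log2 delta. Genes whose post-TES window overlaps
#' another annotated gene's span are flagged (not dropped).
#'
#' @param cov_ctrl,cov_dep \code{stranded_coverage} tracks sharing
#'   normalisation.
#' @param genes gene models.
#' @param params [analysis_params()].
#' @param tpm optional named vector of control TPM per gene_id; when given,
#'   genes with TPM < tpm_min are excluded.
#' @param apply_neighbour_filter apply [filter_nonneighbouring()] first.
#' @param denominator passed to [readthrough_record()].
#' @return data.frame: gene_id, chrom, strand, body_mean_ctrl, body_mean_dep,
#'   post_tes_mean_ctrl, post_tes_mean_dep, rt_ctrl, rt_dep, delta_log2,
#'   post_tes_overlaps_gene.
#' @export
readthrough_table <- function(cov_ctrl, cov_dep, genes,
                              params = analysis_params(), tpm = NULL,
                              apply_neighbour_filter = TRUE,
                              denominator = "body") {
  if (cov_ctrl$normalisation != cov_dep$normalisation) {
    stop("tracks must share normalisation")
  }
  all_genes <- genes
  if (apply_neighbour_filter) genes <- filter_nonneighbouring(genes, params)
  if (!is.null(tpm)) {
    keep <- !is.na(tpm[genes$gene_id]) & tpm[genes$gene_id] >= params$tpm_min
    genes <- genes[keep, , drop = FALSE]
  }
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), body_mean_ctrl = numeric(),
                      body_mean_dep = numeric(),
                      post_tes_mean_ctrl = numeric(),
                      post_tes_mean_dep = numeric(), rt_ctrl = numeric(),
                      rt_dep = numeric(), delta_log2 = numeric(),
                      post_tes_overlaps_gene = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0) {
    message("readthrough_table: no genes pass the filters")
    return(empty)
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    rc <- readthrough_record(cov_ctrl, g, params, denominator, "control")
    rd <- readthrough_record(cov_dep, g, params, denominator, "depleted")
    if (is.null(rc) || is.null(rd)) return(NULL)
    t_end <- tes(g)[[1]]
    post <- if (g$strand == "+") c(t_end, t_end + params$post_tes_window)
            else c(t_end - params$post_tes_window, t_end)
    others <- all_genes$gene_id != g$gene_id & all_genes$chrom == g$chrom
    overlaps <- any(all_genes$start[others] < post[2] &
                    all_genes$end[others] > post[1])
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               body_mean_ctrl = rc$body_mean, body_mean_dep = rd$body_mean,
               post_tes_mean_ctrl = rc$post_tes_mean,
               post_tes_mean_dep = rd$post_tes_mean,
               rt_ctrl = rc$rt_index, rt_dep = rd$rt_index,
               delta_log2 = readthrough_delta(rc, rd),
               post_tes_overlaps_gene = overlaps,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_log2, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
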
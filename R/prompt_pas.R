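#' Define PROMPT windows upstream of gene promoters
#'
#' For a + strand gene the PROMPT window is \code{[TSS - w, TSS)} on the -
#' strand; mirrored for - genes. Windows are clipped at the chromosome start
#' (and end, when \code{chrom_lengths} is supplied); windows overlapping any
#' other gene's span are dropped with a warning. Genes should already be
#' filtered to the expressed, non-neighbouring cohort.
#'
#' @param genes gene models.
#' @param window_bp window length (default the \code{prompt_window} of
#'   [analysis_params()], 3000 bp).
#' @param chrom_lengths optional named vector for clipping at chromosome
#'   ends.
#' @return data.frame: prompt_id, parent_gene, chrom, start, end, strand
#'   (opposite to the parent gene).
#' @export
define_prompt_windows <- function(genes, window_bp = 3000L,
                                  chrom_lengths = NULL) {
  t <- tss(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0, t - window_bp), t)
  end <- ifelse(plus, t, t + window_bp)
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, chrom_lengths[genes$chrom])
  }
  out <- data.frame(prompt_id = paste0(genes$gene_id, "_PROMPT"),
                    parent_gene = genes$gene_id,
                    chrom = genes$chrom,
                    start = start, end = end,
                    strand = ifelse(plus, "-", "+"),
                    stringsAsFactors = FALSE)
  valid <- out$start < out$end
  overlaps <- vapply(seq_len(nrow(out)), function(i) {
    others <- genes$chrom == out$chrom[i] &
      genes$gene_id != out$parent_gene[i]
    any(genes$start[others] < out$end[i] & genes$end[others] > out$start[i])
  }, TRUE)
  drop <- !valid | overlaps
  if (any(drop)) {
    warning(sum(drop), " PROMPT window(s) dropped (empty after clipping or ",
            "overlapping another gene)")
  }
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PROMPT fold change between conditions
#'
#' Mean coverage on the window's own strand (the PROMPT's transcription
#' strand) in each condition, log2 fold change with pseudocount, and the
#' upregulated class (\code{log2fc >= log2fc_up_threshold}, inclusive, so a
#' fold change of exactly 1.0 log2 units is classed upregulated).
#'
#' @param prompts output of [define_prompt_windows()].
#' @param cov_ctrl,cov_cond tracks sharing normalisation.
#' @param params [analysis_params()].
#' @return \code{prompts} with columns \code{signal_ctrl},
#'   \code{signal_cond}, \code{log2fc}, \code{upregulated} added.
#' @export
prompt_fc <- function(prompts, cov_ctrl, cov_cond,
                      params = analysis_params()) {
  if (cov_ctrl$normalisation != cov_cond$normalisation) {
    stop("tracks must share normalisation")
  }
  n <- nrow(prompts)
  sc <- sd <- numeric(n)
  for (i in seq_len(n)) {
    reg <- prompts[i, , drop = FALSE]
    sc[i] <- region_mean(cov_ctrl, reg, "sense")
    sd[i] <- region_mean(cov_cond, reg, "sense")
  }
  prompts$signal_ctrl <- sc
  prompts$signal_cond <- sd
  prompts$log2fc <- log2_ratio(sd, sc, params$pseudocount)
  prompts$upregulated <- prompts$log2fc >= params$log2fc_up_threshold
  prompts
}

#' Scan a sequence for the AWTAAA polyadenylation signal
#'
#' Reports the 0-based start offsets of every occurrence of the consensus
#' hexamer AWTAAA (W = A or T, i.e. AATAAA or ATTAAA), including overlapping
#' occurrences, on the given strand only; callers supply the
#' transcript-sense sequence (reverse-complemented for minus-strand
#' windows). N never matches. Case-insensitive.
#'
#' @param sequence character string or \code{Biostrings::DNAString} over
#'   A, C, G, T, N.
#' @return increasing integer vector of 0-based offsets (empty for
#'   sequences shorter than 6).
#' @export
scan_pas <- function(sequence) {
  if (is.character(sequence)) {
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  if (length(sequence) < 6) return(integer(0))
  m <- Biostrings::matchPattern("AWTAAA", sequence, fixed = "subject")
  sort(BiocGenerics::start(m) - 1L)
}

#' Polyadenylation-signal density over PROMPT windows
#'
#' Extracts each window's sequence in transcript orientation, scans for
#' AWTAAA and reports sites per kb, using the realised (possibly clipped)
#' window length as denominator.
#'
#' @param prompts output of [define_prompt_windows()].
#' @param genome named \code{Biostrings::DNAStringSet} or path to a FASTA
#'   file.
#' @return data.frame: prompt_id, length_bp, n_sites, density_per_kb, with a
#'   list-column \code{positions} of 0-based transcript-sense offsets.
#' @export
pas_density <- function(prompts, genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  missing_ch <- setdiff(unique(prompts$chrom), names(genome))
  if (length(missing_ch)) {
    stop("chromosome absent from genome: ", missing_ch[1])
  }
  res <- lapply(seq_len(nrow(prompts)), function(i) {
    s <- Biostrings::subseq(genome[[prompts$chrom[i]]],
                            prompts$start[i] + 1L, prompts$end[i])
    if (prompts$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    scan_pas(s)
  })
  len <- prompts$end - prompts$start
  n_sites <- lengths(res)
  out <- data.frame(prompt_id = prompts$prompt_id,
                    length_bp = len,
                    n_sites = n_sites,
                    density_per_kb = n_sites / (len / 1000),
                    stringsAsFactors = FALSE)
  out$positions <- res
  out
}

#' Split PAS densities by PROMPT upregulation class
#'
#' Partitions densities into the upregulated and not-upregulated PROMPT
#' groups (exhaustive and disjoint) and summarises each.
#'
#' @param densities output of [pas_density()].
#' @param prompts output of [prompt_fc()] (must carry \code{upregulated}).
#' @return list with \code{summary} (data.frame: class, n, median_density,
#'   mean_density; NA summaries for an empty group) and \code{by_class}
#'   (named list of the two density subsets).
#' @export
split_density_by_class <- function(densities, prompts) {
  if (is.null(prompts$upregulated)) {
    stop("prompts lack the upregulated class; run prompt_fc first")
  }
  up_ids <- prompts$prompt_id[prompts$upregulated]
  cls <- ifelse(densities$prompt_id %in% up_ids,
                "upregulated", "not_upregulated")
  by_class <- split(densities, factor(cls, levels = c("upregulated",
                                                      "not_upregulated")))
  summary <- do.call(rbind, lapply(names(by_class), function(k) {
    d <- by_class[[k]]$density_per_kb
    data.frame(class = k, n = length(d),
               median_density = if (length(d)) stats::median(d) else NA_real_,
               mean_density = if (length(d)) mean(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, by_class = by_class)
}

#' Estimate the extent of antisense (PROMPT) transcription upstream of a TSS
#'
#' Walks upstream of the gene's TSS on the antisense strand in fixed bins
#' and returns the distance (bp) from the TSS to the far edge of the
#' furthest bin whose mean coverage reaches \code{threshold}. By default the
#' threshold is half the mean of the first \code{baseline_bins} bins
#' (promoter-proximal PROMPT level), the half-maximum rule.
#'
#' @param cov \code{stranded_coverage}.
#' @param gene one-row gene models subset.
#' @param max_extent bp to scan (clipped at the chromosome edge).
#' @param bin bp per scan bin.
#' @param baseline_bins bins used for the half-maximum baseline.
#' @param threshold optional explicit coverage threshold.
#' @return extent in bp (0 when no bin reaches the threshold).
#' @export
estimate_prompt_extent <- function(cov, gene, max_extent = 10000L, bin = 50L,
                                   baseline_bins = 10L, threshold = NULL) {
  t <- tss(gene)[[1]]
  chrom <- gene$chrom[1]
  .check_chrom(cov, chrom)
  len <- cov$chrom_lengths[[chrom]]
  avail <- if (gene$strand[1] == "+") t else len - t
  max_extent <- min(max_extent, avail)
  nb <- as.integer(max_extent %/% bin)
  if (nb < 1) return(0)
  span <- nb * bin
  if (gene$strand[1] == "+") {
    v <- .oriented_values(cov, chrom, t - span, t, "+", "antisense")
  } else {
    v <- .oriented_values(cov, chrom, t, t + span, "-", "antisense")
  }
  # v runs 5'->3' along the gene, i.e. from far upstream towards the TSS on
  # + genes; reorient so index 1 is the bin nearest the TSS
  means <- rev(colMeans(matrix(v, nrow = bin)))
  if (is.null(threshold)) {
    threshold <- mean(means[seq_len(min(baseline_bins, nb))]) / 2
  }
  hit <- which(means >= threshold & threshold > 0)
  if (!length(hit)) return(0)
  max(hit) * bin
}
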
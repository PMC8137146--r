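# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (IRanges, Biostrings) so that agreement is informative.

# random unstranded interval set on a single small chromosome
random_interval_set <- function(n, chrom_len, chrom = "chr1") {
  start <- sample.int(chrom_len - 2L, n, replace = TRUE) - 1L
  width <- sample.int(200L, n, replace = TRUE)
  end <- pmin(start + width, chrom_len)
  genomic_intervals(chrom, start, end)
}

# per-base membership oracle: mark covered bases, combine, re-segment
oracle_base_op <- function(a, b, chrom_len, op = c("and", "andnot")) {
  op <- match.arg(op)
  cover <- function(x) {
    v <- logical(chrom_len)
    for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
    v
  }
  va <- cover(a)
  vb <- cover(b)
  v <- if (op == "and") va & vb else va & !vb
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(chrom = "chr1", start = starts[keep], end = ends[keep],
             strand = "*", stringsAsFactors = FALSE)
}

# naive per-base pileup oracle (bin size 1)
oracle_pileup <- function(reads, chrom_len, strand) {
  v <- numeric(chrom_len)
  sel <- which(reads$strand == strand)
  for (i in sel) v[(reads$start[i] + 1):reads$end[i]] <-
      v[(reads$start[i] + 1):reads$end[i]] + 1
  v
}

# exhaustive read-vs-exon overlap count for one gene
oracle_count_exonic <- function(reads, gene) {
  ex <- gene$exons[[1]]
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != gene$chrom[1] ||
        reads$strand[i] != gene$strand[1]) next
    hit <- FALSE
    for (j in seq_len(nrow(ex))) {
      if (reads$start[i] < ex$end[j] && reads$end[i] > ex$start[j]) {
        hit <- TRUE
        break
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

# exhaustive 6-mer window scan for AWTAAA (0-based offsets)
oracle_scan_pas <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6) return(integer(0))
  words <- substring(seq, 1:(n - 5), 6:n)
  which(words %in% c("AATAAA", "ATTAAA")) - 1L
}

# rank-based AUROC of score against logical labels
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# constant-value coverage track builder
constant_coverage <- function(chrom_lengths, value, bin_size = 1L) {
  cov <- stranded_coverage(chrom_lengths, bin_size)
  for (slot in c("plus", "minus")) {
    cov[[slot]] <- lapply(cov[[slot]], function(v) v + value)
  }
  cov
}
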
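# oriented per-base values over [start, end) plus logical on-chromosome mask;
# off-chromosome positions are NA; 5'->3' orientation (reversed for - regions)
.oriented_values <- function(cov, chrom, start, end, strand, strand_mode) {
  .check_chrom(cov, chrom)
  len <- cov$chrom_lengths[[chrom]]
  pos <- seq.int(start, end - 1)
  v <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & pos < len
  if (any(ok)) {
    idx <- pos[ok] %/% cov$bin_size + 1L
    slots <- .resolve_strand(strand, strand_mode)
    acc <- 0
    for (slot in slots) acc <- acc + cov[[slot]][[chrom]][idx]
    v[ok] <- acc
  }
  if (strand == "-") v <- rev(v)
  v
}

# means of v over half-open index windows given by 0-based boundary vector b
.segment_means <- function(v, b) {
  fin <- !is.na(v)
  cs <- c(0, cumsum(ifelse(fin, v, 0)))
  cn <- c(0, cumsum(fin))
  lo <- b[-length(b)]
  hi <- b[-1]
  tot <- cs[hi + 1] - cs[lo + 1]
  cnt <- cn[hi + 1] - cn[lo + 1]
  list(mean = ifelse(cnt > 0, tot / cnt, 0), complete = cnt == (hi - lo))
}

#' Scaled-region coverage matrix
#'
#' Builds a regions x columns matrix in the scale-regions style: fixed-width
#' flank bins on each side and a body rescaled to \code{body_bins}
#' equal-width genomic slices (mean per slice, no interpolation). Rows of
#' minus-strand regions are reversed so columns always run 5' to 3'.
#' Off-chromosome flank positions contribute 0 and are masked; regions
#' shorter than \code{body_bins} bp are fully masked with a warning.
#'
#' @param cov \code{stranded_coverage}.
#' @param regions gene models or interval table (unstranded intervals are
#'   not reversed and, under \code{"sense"}, use both strands).
#' @param body_bins number of body slices.
#' @param flank bp of flank each side (must be a multiple of
#'   \code{bin_size}).
#' @param bin_size bp per flank bin.
#' @param strand_mode \code{"sense"}, \code{"antisense"} or \code{"both"}.
#' @return list of class \code{metagene_matrix}: \code{values} (matrix, 0
#'   where masked), \code{mask} (TRUE = cell complete), \code{region_ids},
#'   and the geometry parameters.
#' @export
build_matrix <- function(cov, regions, body_bins = 100L, flank = 3000L,
                         bin_size = 10L,
                         strand_mode = c("sense", "antisense", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (nrow(regions) == 0) stop("regions must be non-empty")
  if (body_bins < 1) stop("body_bins must be >= 1")
  if (flank %% bin_size != 0) stop("flank must be a multiple of bin_size")
  nfl <- flank %/% bin_size
  ncol_out <- 2L * nfl + body_bins
  ids <- if ("gene_id" %in% names(regions)) regions$gene_id
         else if ("name" %in% names(regions) && !anyNA(regions$name)) {
           regions$name
         } else sprintf("%s:%d-%d", regions$chrom,
                        as.integer(regions$start), as.integer(regions$end))
  values <- matrix(0, nrow(regions), ncol_out)
  mask <- matrix(FALSE, nrow(regions), ncol_out)
  short <- 0L
  for (i in seq_len(nrow(regions))) {
    L <- regions$end[i] - regions$start[i]
    if (L < body_bins) { short <- short + 1L; next }
    v <- .oriented_values(cov, regions$chrom[i],
                          regions$start[i] - flank, regions$end[i] + flank,
                          regions$strand[i], strand_mode)
    b <- c(seq.int(0L, flank, by = bin_size)[-(nfl + 1L)],
           flank + floor((0:body_bins) * L / body_bins)[-(body_bins + 1L)],
           flank + L + seq.int(0L, flank, by = bin_size))
    seg <- .segment_means(v, b)
    values[i, ] <- seg$mean
    mask[i, ] <- seg$complete
  }
  if (short > 0) {
    warning(short, " region(s) shorter than body_bins bp were masked")
  }
  structure(list(values = values, mask = mask, region_ids = ids,
                 body_bins = as.integer(body_bins), flank = as.integer(flank),
                 bin_size = as.integer(bin_size), strand_mode = strand_mode),
            class = "metagene_matrix")
}

#' Strand-split average metagene profile
#'
#' Column means of the sense-strand matrix, and of the antisense-strand
#' matrix multiplied by -1 so that, when plotted, positive signal is sense
#' and negative signal is antisense.
#'
#' @param cov \code{stranded_coverage}.
#' @param genes stranded gene models.
#' @param body_bins,flank,bin_size matrix geometry (see [build_matrix()]).
#' @return data.frame: column position label, \code{sense},
#'   \code{antisense} (already scaled to -1); attribute \code{n} = number
#'   of regions.
#' @export
strand_split_profile <- function(cov, genes, body_bins = 100L, flank = 3000L,
                                 bin_size = 10L) {
  ms <- build_matrix(cov, genes, body_bins, flank, bin_size, "sense")
  ma <- build_matrix(cov, genes, body_bins, flank, bin_size, "antisense")
  nfl <- flank %/% bin_size
  out <- data.frame(
    column = seq_len(2L * nfl + body_bins),
    segment = rep(c("upstream", "body", "downstream"),
                  c(nfl, body_bins, nfl)),
    sense = colMeans(ms$values),
    antisense = -colMeans(ma$values))
  attr(out, "n") <- nrow(genes)
  out
}

#' Super-enhancer log-ratio metaplot with bootstrap halo
#'
#' For each region and column computes \code{log2((num + p)/(den + p))} on
#' both-strands-summed signal (enhancer RNA is bidirectional), averages
#' across regions, and derives a percentile-bootstrap confidence halo by
#' resampling regions.
#'
#' @param cov_num,cov_den numerator (e.g. depletion/experiment) and
#'   denominator (control/input) tracks sharing normalisation.
#' @param se_regions interval table (unstranded).
#' @param body_bins,flank,bin_size matrix geometry.
#' @param n_boot bootstrap resamples (default 1000).
#' @param pseudocount added to both tracks in the ratio.
#' @param conf_level halo confidence level (default 0.95).
#' @param seed optional seed for the bootstrap (caller RNG is untouched).
#' @return data.frame: column, segment, log2_ratio_mean, ci_low, ci_high
#'   (CIs NA with a warning when fewer than 2 regions are given);
#'   attribute \code{n} = number of regions.
#' @export
se_metaplot <- function(cov_num, cov_den, se_regions, body_bins = 100L,
                        flank = 3000L, bin_size = 10L, n_boot = 1000L,
                        pseudocount = 0.01, conf_level = 0.95, seed = NULL) {
  if (cov_num$normalisation != cov_den$normalisation) {
    stop("tracks must share normalisation")
  }
  mn <- build_matrix(cov_num, se_regions, body_bins, flank, bin_size, "both")
  md <- build_matrix(cov_den, se_regions, body_bins, flank, bin_size, "both")
  r <- log2((mn$values + pseudocount) / (md$values + pseudocount))
  nfl <- flank %/% bin_size
  out <- data.frame(
    column = seq_len(ncol(r)),
    segment = rep(c("upstream", "body", "downstream"),
                  c(nfl, body_bins, nfl)),
    log2_ratio_mean = colMeans(r),
    ci_low = NA_real_, ci_high = NA_real_)
  if (nrow(r) < 2) {
    warning("fewer than 2 regions: confidence halo undefined")
  } else {
    boot <- .with_seed(seed, {
      idx <- matrix(sample.int(nrow(r), nrow(r) * n_boot, replace = TRUE),
                    nrow = n_boot)
      t(apply(idx, 1, function(j) colMeans(r[j, , drop = FALSE])))
    })
    alpha <- (1 - conf_level) / 2
    qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    out$ci_low <- qs[1, ]
    out$ci_high <- qs[2, ]
  }
  attr(out, "n") <- nrow(se_regions)
  out
}
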
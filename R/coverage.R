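#' Construct an empty stranded coverage track
#'
#' Per-chromosome numeric vectors for each strand at a fixed bin size, with a
#' normalisation tag. Bin \code{i} (0-based) covers bases
#' \code{[i*bin_size, min((i+1)*bin_size, chrom_length))}.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bp per bin (default 1).
#' @param normalisation \code{"raw"}, \code{"RPKM"} or \code{"CPM"}.
#' @param library_size total read count behind the track (NA for tracks not
#'   derived from reads).
#' @return object of class \code{stranded_coverage}.
#' @export
stranded_coverage <- function(chrom_lengths, bin_size = 1L,
                              normalisation = "raw", library_size = NA_real_) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named")
  }
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  if (bin_size < 1) stop("bin_size must be >= 1")
  nbins <- ceiling(chrom_lengths / bin_size)
  mk <- function() lapply(nbins, numeric)
  structure(list(chrom_lengths = chrom_lengths,
                 bin_size = as.integer(bin_size),
                 plus = mk(), minus = mk(),
                 normalisation = normalisation,
                 library_size = library_size),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat(sprintf("stranded_coverage: %d chrom(s), bin_size %d, %s%s\n",
              length(x$chrom_lengths), x$bin_size, x$normalisation,
              if (is.na(x$library_size)) ""
              else sprintf(", library_size %g", x$library_size)))
  invisible(x)
}

.check_chrom <- function(cov, chrom) {
  if (!chrom %in% names(cov$chrom_lengths)) {
    stop("unknown chromosome: ", chrom)
  }
}

#' Pile up stranded reads into a coverage track
#'
#' Each read increments every bin it overlaps by at least one base, on its
#' own strand. \code{library_size} is set to the number of reads.
#'
#' @param reads interval table with strand \code{"+"}/\code{"-"}.
#' @param chrom_lengths named numeric vector.
#' @param bin_size bp per bin.
#' @return raw \code{stranded_coverage}.
#' @export
coverage_from_reads <- function(reads, chrom_lengths, bin_size = 1L) {
  validate_intervals(reads)
  if (any(!reads$strand %in% c("+", "-"))) {
    stop("reads must be stranded ('+' or '-')")
  }
  unknown <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(unknown)) stop("read on unknown chromosome: ", unknown[1])
  lens <- chrom_lengths[reads$chrom]
  if (any(reads$end > lens)) stop("read beyond chromosome end")
  cov <- stranded_coverage(chrom_lengths, bin_size,
                           normalisation = "raw",
                           library_size = nrow(reads))
  for (ch in unique(reads$chrom)) {
    nb <- length(cov$plus[[ch]])
    for (s in c("+", "-")) {
      sel <- reads$chrom == ch & reads$strand == s
      if (!any(sel)) next
      b0 <- reads$start[sel] %/% bin_size
      b1 <- (reads$end[sel] - 1) %/% bin_size
      ir <- IRanges::IRanges(start = b0 + 1L, end = b1 + 1L)
      v <- as.numeric(IRanges::coverage(ir, width = nb))
      slot <- if (s == "+") "plus" else "minus"
      cov[[slot]][[ch]] <- cov[[slot]][[ch]] + v
    }
  }
  cov
}

.scale_coverage <- function(cov, factor, tag) {
  for (slot in c("plus", "minus")) {
    cov[[slot]] <- lapply(cov[[slot]], function(v) v * factor)
  }
  cov$normalisation <- tag
  cov
}

#' RPKM-normalise a raw coverage track
#'
#' Each bin value v becomes \code{v * 1e9 / (library_size * bin_size)}
#' (reads per kilobase per million mapped reads, at the track's bin size).
#'
#' @param cov raw \code{stranded_coverage} with \code{library_size > 0}.
#' @return RPKM-tagged track.
#' @export
normalise_rpkm <- function(cov) {
  if (cov$normalisation != "raw") stop("track is already normalised")
  if (is.na(cov$library_size) || cov$library_size <= 0) {
    stop("library_size must be > 0 for RPKM")
  }
  .scale_coverage(cov, 1e9 / (cov$library_size * cov$bin_size), "RPKM")
}

#' CPM-normalise a raw coverage track (v * 1e6 / library_size)
#' @param cov raw \code{stranded_coverage} with \code{library_size > 0}.
#' @return CPM-tagged track.
#' @export
normalise_cpm <- function(cov) {
  if (cov$normalisation != "raw") stop("track is already normalised")
  if (is.na(cov$library_size) || cov$library_size <= 0) {
    stop("library_size must be > 0 for CPM")
  }
  .scale_coverage(cov, 1e6 / cov$library_size, "CPM")
}

# resolve which strand vector(s) a query uses
.resolve_strand <- function(region_strand, strand_mode) {
  if (strand_mode == "both" || region_strand == "*") return(c("plus", "minus"))
  flip <- strand_mode == "antisense"
  s <- if (region_strand == "+") !flip else flip
  if (s) "plus" else "minus"
}

#' Mean coverage over a region
#'
#' The region is clipped to the chromosome; the mean is taken over the bins
#' the clipped region touches. Strand resolution: \code{"sense"} uses the
#' region's own strand, \code{"antisense"} the opposite, \code{"both"} the
#' sum of strands (also used for unstranded regions).
#'
#' @param cov \code{stranded_coverage}.
#' @param region single-row interval table or list with chrom/start/end/strand.
#' @param strand_mode \code{"sense"}, \code{"antisense"} or \code{"both"}.
#' @return non-negative scalar.
#' @export
region_mean <- function(cov, region, strand_mode = c("sense", "antisense",
                                                     "both")) {
  strand_mode <- match.arg(strand_mode)
  chrom <- as.character(region$chrom[1])
  .check_chrom(cov, chrom)
  len <- cov$chrom_lengths[[chrom]]
  st <- max(0, region$start[1])
  en <- min(len, region$end[1])
  if (st >= en) stop("region entirely outside chromosome: ", chrom)
  b0 <- st %/% cov$bin_size
  b1 <- (en - 1) %/% cov$bin_size
  slots <- .resolve_strand(as.character(region$strand[1]), strand_mode)
  v <- 0
  for (slot in slots) v <- v + cov[[slot]][[chrom]][(b0 + 1):(b1 + 1)]
  mean(v)
}

#' Read a pair of bedGraph files into a stranded track
#'
#' Regions absent from the files are zero. Records must lie within the
#' chromosome, align to bin boundaries, and not overlap each other.
#' An empty or missing-value file yields an all-zero strand.
#'
#' @param path_plus,path_minus bedGraph paths for the two strands.
#' @param chrom_lengths named numeric vector.
#' @param bin_size bp per bin.
#' @param normalisation tag recorded on the track.
#' @param library_size optional library size to record.
#' @return \code{stranded_coverage}.
#' @export
read_bedgraph <- function(path_plus, path_minus, chrom_lengths, bin_size = 1L,
                          normalisation = "raw", library_size = NA_real_) {
  cov <- stranded_coverage(chrom_lengths, bin_size, normalisation,
                           library_size)
  fill <- function(path, slot) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0) return()
    lines <- readLines(path)
    keep <- which(!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines)))
    if (!length(keep)) return()
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 4)) {
      stop("bedGraph line ", keep[which(nf < 4)[1]], ": fewer than 4 fields")
    }
    m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4, byrow = TRUE)
    ch <- m[, 1]
    st <- suppressWarnings(as.numeric(m[, 2]))
    en <- suppressWarnings(as.numeric(m[, 3]))
    val <- suppressWarnings(as.numeric(m[, 4]))
    bad <- is.na(st) | is.na(en) | is.na(val)
    if (any(bad)) stop("bedGraph line ", keep[which(bad)[1]], ": bad fields")
    unknown <- !ch %in% names(chrom_lengths)
    if (any(unknown)) {
      stop("bedGraph line ", keep[which(unknown)[1]],
           ": unknown chromosome ", ch[which(unknown)[1]])
    }
    lens <- chrom_lengths[ch]
    if (any(en > lens)) {
      stop("bedGraph line ", keep[which(en > lens)[1]],
           ": record beyond chromosome length")
    }
    misaligned <- st %% bin_size != 0 |
      (en %% bin_size != 0 & en != lens)
    if (any(misaligned)) {
      stop("bedGraph line ", keep[which(misaligned)[1]],
           ": record not aligned to bin_size")
    }
    for (c1 in unique(ch)) {
      sel <- which(ch == c1)
      o <- sel[order(st[sel])]
      if (length(o) > 1 &&
          any(st[o][-1] < en[o][-length(o)])) {
        bad_i <- o[which(st[o][-1] < en[o][-length(o)])[1] + 1]
        stop("bedGraph line ", keep[bad_i], ": overlapping records")
      }
      b0 <- st[o] %/% bin_size
      b1 <- (en[o] - 1) %/% bin_size
      nb <- b1 - b0 + 1
      idx <- sequence(nb, from = b0 + 1)
      cov[[slot]][[c1]][idx] <<- rep(val[o], nb)
    }
  }
  fill(path_plus, "plus")
  fill(path_minus, "minus")
  cov
}

#' Write a stranded track as two bedGraph files
#'
#' Emits \code{<prefix>.plus.bedgraph} and \code{<prefix>.minus.bedgraph},
#' run-length encoded, zero runs omitted; lossless at the track's bin size.
#'
#' @param cov \code{stranded_coverage}.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_bedgraph <- function(cov, prefix) {
  out <- c(plus = paste0(prefix, ".plus.bedgraph"),
           minus = paste0(prefix, ".minus.bedgraph"))
  for (slot in c("plus", "minus")) {
    con <- file(out[[slot]], "w")
    for (ch in names(cov$chrom_lengths)) {
      v <- cov[[slot]][[ch]]
      r <- rle(v)
      ends_bin <- cumsum(r$lengths)
      starts_bin <- ends_bin - r$lengths
      nz <- r$values != 0
      if (any(nz)) {
        st <- starts_bin[nz] * cov$bin_size
        en <- pmin(ends_bin[nz] * cov$bin_size, cov$chrom_lengths[[ch]])
        writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(st),
                           as.integer(en),
                           format(r$values[nz], scientific = FALSE,
                                  trim = TRUE, digits = 15)),
                   con)
      }
    }
    close(con)
  }
  invisible(out)
}

#' Write a chromosome-sizes file (two-column TSV)
#' @param chrom_lengths named numeric vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_lengths, path) {
  writeLines(sprintf("%s\t%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), path)
  invisible(path)
}

#' Read a chromosome-sizes file
#' @param path two-column TSV (chrom, length).
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$length, tab$chrom)
}
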
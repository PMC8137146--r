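#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with columns \code{chrom}, \code{start},
#' \code{end}, \code{strand}, using 0-based half-open coordinates throughout
#' (BED convention). Strand is one of \code{"+"}, \code{"-"} or \code{"*"}
#' (unstranded).
#'
#' @param chrom character vector of chromosome names (non-empty).
#' @param start,end integer vectors, 0-based half-open; \code{start < end}.
#' @param strand character vector, recycled; \code{"+"}, \code{"-"} or
#'   \code{"*"}.
#' @return data.frame with class \code{c("genomic_intervals", "data.frame")}.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  n <- length(chrom)
  strand <- rep_len(as.character(strand), n)
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  strand = strand,
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

validate_intervals <- function(x) {
  req <- c("chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("interval table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) stop("chrom must be non-empty")
  if (any(!is.finite(x$start) | !is.finite(x$end))) {
    stop("non-finite interval coordinates")
  }
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end")
  if (any(!x$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  invisible(x)
}

# split a (chrom,start,end) table into an IRanges per chromosome, 1-based
.irl_by_chrom <- function(x, chroms) {
  lapply(chroms, function(ch) {
    sel <- x$chrom == ch
    IRanges::IRanges(start = x$start[sel] + 1L, end = x$end[sel])
  })
}

.ir_to_df <- function(ir, chrom) {
  if (length(ir) == 0) return(NULL)
  data.frame(chrom = chrom, start = BiocGenerics::start(ir) - 1,
             end = BiocGenerics::end(ir), strand = "*",
             stringsAsFactors = FALSE)
}

.bind_intervals <- function(parts) {
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, parts)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Merge overlapping or adjacent intervals
#'
#' Strand is ignored; output is sorted, non-overlapping, unstranded.
#'
#' @param x interval table.
#' @return merged interval table.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  chroms <- sort(unique(x$chrom))
  irl <- .irl_by_chrom(x, chroms)
  .bind_intervals(mapply(function(ir, ch) .ir_to_df(IRanges::reduce(ir), ch),
                         irl, chroms, SIMPLIFY = FALSE))
}

#' Base-level intersection of two interval sets
#'
#' Returns the bases covered by both the union of \code{a} and the union of
#' \code{b}, merged and sorted. Strand is ignored (peak sets are unstranded);
#' this is the replicate-intersection step used to derive high-confidence
#' peak sets from individual ChIP replicates.
#'
#' @param a,b interval tables.
#' @return merged, sorted, unstranded interval table.
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  chroms <- sort(intersect(unique(a$chrom), unique(b$chrom)))
  ira <- .irl_by_chrom(a, chroms)
  irb <- .irl_by_chrom(b, chroms)
  .bind_intervals(mapply(function(x, y, ch) {
    .ir_to_df(IRanges::intersect(IRanges::reduce(x), IRanges::reduce(y)), ch)
  }, ira, irb, chroms, SIMPLIFY = FALSE))
}

#' Base-level subtraction of one interval set from another
#'
#' Returns the bases of \code{a} not covered by \code{b} (input-subtraction
#' step for ChIP peak sets), merged and sorted; strand ignored.
#'
#' @param a,b interval tables.
#' @return merged, sorted, unstranded interval table.
#' @export
subtract_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  chroms <- sort(unique(a$chrom))
  ira <- .irl_by_chrom(a, chroms)
  irb <- .irl_by_chrom(b, chroms)
  .bind_intervals(mapply(function(x, y, ch) {
    .ir_to_df(IRanges::setdiff(IRanges::reduce(x), IRanges::reduce(y)), ch)
  }, ira, irb, chroms, SIMPLIFY = FALSE))
}

#' Read a BED3/BED6 file
#'
#' Coordinates are kept verbatim (BED is already 0-based half-open). A
#' missing or \code{"."} strand field becomes \code{"*"}. Malformed lines
#' (fewer than 3 fields, non-integer coordinates, start >= end, unknown
#' strand) raise an error naming the offending line number. \code{track},
#' \code{browser} and \code{#} comment lines are skipped.
#'
#' @param path file path.
#' @return interval table in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  rec <- function(i) {
    f <- parts[[i]]
    ln <- idx[i]
    if (length(f) < 3) stop("BED line ", ln, ": fewer than 3 fields")
    st <- suppressWarnings(as.numeric(f[2]))
    en <- suppressWarnings(as.numeric(f[3]))
    if (is.na(st) || is.na(en) || st != floor(st) || en != floor(en)) {
      stop("BED line ", ln, ": non-integer coordinates")
    }
    if (st < 0 || st >= en) stop("BED line ", ln, ": requires 0 <= start < end")
    strand <- if (length(f) >= 6) f[6] else "."
    if (strand == ".") strand <- "*"
    if (!strand %in% c("+", "-", "*")) {
      stop("BED line ", ln, ": unknown strand '", strand, "'")
    }
    list(chrom = f[1], start = st, end = en, strand = strand,
         name = if (length(f) >= 4) f[4] else NA_character_)
  }
  recs <- lapply(seq_along(idx), rec)
  out <- genomic_intervals(vapply(recs, `[[`, "", "chrom"),
                           vapply(recs, `[[`, 0, "start"),
                           vapply(recs, `[[`, 0, "end"),
                           vapply(recs, `[[`, "", "strand"))
  out$name <- vapply(recs, `[[`, "", "name")
  out
}

#' Write intervals as BED6
#'
#' @param x interval table (optional \code{name} column used if present).
#' @param path output file path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  nm <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  strand <- ifelse(x$strand == "*", ".", x$strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end), nm, strand)
  writeLines(lines, path)
  invisible(path)
}
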
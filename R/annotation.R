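#' Construct gene models
#'
#' A gene model is a stranded span plus an ordered exon structure. Models are
#' stored as a data frame (one row per gene) with a list-column \code{exons};
#' each element is a two-column data frame (\code{start}, \code{end}), sorted,
#' pairwise non-overlapping, contained in the span. Coordinates are 0-based
#' half-open. Genes with no exon structure get a single exon equal to the
#' span.
#'
#' @param gene_id character vector of unique identifiers.
#' @param chrom,start,end,strand span coordinates; strand must be
#'   \code{"+"} or \code{"-"}.
#' @param biotype label, recycled.
#' @param exons optional list (one element per gene) of data frames with
#'   \code{start}/\code{end} columns.
#' @return data.frame with class \code{c("gene_models", "data.frame")}.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        biotype = "protein_coding", exons = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  g <- data.frame(gene_id = as.character(gene_id),
                  chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  strand = rep_len(as.character(strand), n),
                  biotype = rep_len(as.character(biotype), n),
                  stringsAsFactors = FALSE)
  if (any(!g$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(g$start < 0 | g$start >= g$end)) {
    stop("gene spans must satisfy 0 <= start < end")
  }
  if (is.null(exons)) {
    exons <- lapply(seq_len(n), function(i) {
      data.frame(start = g$start[i], end = g$end[i])
    })
  }
  if (length(exons) != n) stop("exons list length must equal number of genes")
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) {
      exons[[i]] <- data.frame(start = g$start[i], end = g$end[i])
      next
    }
    ex <- ex[order(ex$start), c("start", "end"), drop = FALSE]
    rownames(ex) <- NULL
    if (any(ex$start >= ex$end)) {
      stop("gene ", g$gene_id[i], ": empty exon")
    }
    if (any(ex$start < g$start[i] | ex$end > g$end[i])) {
      stop("gene ", g$gene_id[i], ": exon outside gene span")
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("gene ", g$gene_id[i], ": overlapping exons")
    }
    exons[[i]] <- ex
  }
  g$exons <- exons
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Transcription start sites
#'
#' Returns, per gene, the TSS as a half-open boundary coordinate: span start
#' for + genes, span end for - genes. Windows upstream of the TSS are
#' therefore \code{[tss - w, tss)} on + and \code{[tss, tss + w)} on -.
#'
#' @param genes gene models.
#' @return numeric vector named by gene_id.
#' @export
tss <- function(genes) {
  stats::setNames(ifelse(genes$strand == "+", genes$start, genes$end),
                  genes$gene_id)
}

#' Transcription end sites (boundary coordinate; see [tss()])
#' @param genes gene models.
#' @return numeric vector named by gene_id.
#' @export
tes <- function(genes) {
  stats::setNames(ifelse(genes$strand == "+", genes$end, genes$start),
                  genes$gene_id)
}

#' Total exonic length per gene
#' @param genes gene models.
#' @return numeric vector named by gene_id.
#' @export
exonic_length <- function(genes) {
  stats::setNames(vapply(genes$exons, function(ex) sum(ex$end - ex$start), 0),
                  genes$gene_id)
}

#' Read gene annotation (GTF or BED12)
#'
#' GTF records (1-based closed) are converted to internal 0-based half-open
#' coordinates; exon records are grouped per \code{gene_id}. BED12 block
#' structure becomes the exon structure. Exons outside the gene span raise a
#' validation error.
#'
#' @param path file path.
#' @param dialect \code{"gtf"} or \code{"bed12"}.
#' @return gene models.
#' @export
read_annotation <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "gtf") .read_gtf(path) else .read_bed12(path)
}

.read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop("GTF attributes must contain gene_id")
  type <- as.character(md$type)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand[type %in% c("gene", "exon")] %in% c("+", "-"))) {
    stop("unknown strand symbol in GTF gene/exon record")
  }
  st0 <- BiocGenerics::start(gr) - 1
  en0 <- BiocGenerics::end(gr)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  is_gene <- type == "gene"
  is_exon <- type == "exon"
  if (!any(is_gene)) stop("GTF contains no gene records")
  gid <- as.character(md$gene_id)
  exons_by <- split(data.frame(start = st0[is_exon], end = en0[is_exon]),
                    gid[is_exon])
  ids <- gid[is_gene]
  exons <- lapply(ids, function(id) exons_by[[id]])
  gene_models(gene_id = ids, chrom = chrom[is_gene], start = st0[is_gene],
              end = en0[is_gene], strand = strand[is_gene],
              biotype = if (!is.null(md$gene_biotype)) {
                as.character(md$gene_biotype)[is_gene]
              } else "protein_coding",
              exons = exons)
}

.read_bed12 <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines)))
  recs <- lapply(keep, function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("BED12 line ", ln, ": fewer than 12 fields")
    st <- as.numeric(f[2]); en <- as.numeric(f[3])
    if (is.na(st) || is.na(en) || st >= en) {
      stop("BED12 line ", ln, ": bad span coordinates")
    }
    if (!f[6] %in% c("+", "-")) stop("BED12 line ", ln, ": unknown strand")
    nb <- as.integer(f[10])
    sizes <- as.numeric(strsplit(f[11], ",")[[1]])[seq_len(nb)]
    starts <- as.numeric(strsplit(f[12], ",")[[1]])[seq_len(nb)]
    if (anyNA(sizes) || anyNA(starts)) {
      stop("BED12 line ", ln, ": bad block definition")
    }
    list(chrom = f[1], start = st, end = en, name = f[4], strand = f[6],
         exons = data.frame(start = st + starts, end = st + starts + sizes))
  })
  gene_models(gene_id = vapply(recs, `[[`, "", "name"),
              chrom = vapply(recs, `[[`, "", "chrom"),
              start = vapply(recs, `[[`, 0, "start"),
              end = vapply(recs, `[[`, 0, "end"),
              strand = vapply(recs, `[[`, "", "strand"),
              exons = lapply(recs, `[[`, "exons"))
}

#' Write gene models as GTF
#'
#' Emits one \code{gene} record and one \code{exon} record per exon, in
#' 1-based closed GTF coordinates.
#'
#' @param genes gene models.
#' @param path output path.
#' @export
write_gtf <- function(genes, path) {
  fmt <- function(chrom, type, st0, en0, strand, gid, biotype) {
    sprintf(paste0("%s\trtquant\t%s\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; gene_biotype \"%s\";"),
            chrom, type, as.integer(st0) + 1L, as.integer(en0), strand,
            gid, biotype)
  }
  lines <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    c(fmt(genes$chrom[i], "gene", genes$start[i], genes$end[i],
          genes$strand[i], genes$gene_id[i], genes$biotype[i]),
      fmt(genes$chrom[i], "exon", ex$start, ex$end,
          genes$strand[i], genes$gene_id[i], genes$biotype[i]))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Exclude genes with neighbours near their promoter
#'
#' Retains a gene iff no other gene's span overlaps the symmetric window
#' \code{[TSS - d, TSS + d)} with \code{d = neighbour_distance} (default
#' 5 kb). This removes genes with any neighbour close to their promoter,
#' including divergent-promoter pairs, to minimise background in metagene
#' and PROMPT cohorts. A gene never counts as its own neighbour.
#'
#' @param genes gene models.
#' @param params [analysis_params()].
#' @return gene models subset (retained genes, input order); the excluded
#'   gene_ids are available in attribute \code{"excluded"}.
#' @export
filter_nonneighbouring <- function(genes, params = analysis_params()) {
  d <- params$neighbour_distance
  t <- tss(genes)
  win_start <- pmax(0, t - d)
  win_end <- t + d
  keep <- vapply(seq_len(nrow(genes)), function(i) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- setdiff(same, i)
    if (!length(same)) return(TRUE)
    !any(genes$start[same] < win_end[i] & genes$end[same] > win_start[i])
  }, TRUE)
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(genes)
  attr(out, "excluded") <- genes$gene_id[!keep]
  out
}
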
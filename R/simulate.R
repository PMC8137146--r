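#' Specification for a synthetic two-condition dataset
#'
#' Defines the study conditions the generator emulates: a control and a
#' factor-depleted condition over one gene chromosome plus one
#' super-enhancer chromosome. Gene bodies carry a lognormal expression rate
#' floored at 50x coverage; a planted subset of genes gains transcription
#' read-through on depletion (fraction of body rate continuing past the TES
#' with an exponentially decaying tail); every cohort gene carries an
#' antisense PROMPT plateau upstream of its TSS whose extent lengthens on
#' depletion for a planted subset; super-enhancer regions carry bidirectional
#' plateaus whose amplitude rises on depletion; a small set of genes gains
#' sense coverage upstream of the TSS in the depleted condition only
#' (read-through contamination from an upstream unit); PROMPT window
#' sequences are AWTAAA-free except for planted motifs; and a proteomics
#' table plants a minority of ratio-depleted proteins. Per-base Poisson
#' noise is applied unless \code{noise = FALSE}.
#'
#' @param seed master seed; per-stream child seeds are derived by fixed
#'   labelled offsets (annotation +13, genome +11, reads +31, proteomics
#'   +41, coverage +100/+200 plus the replicate index).
#' @param n_genes genes on the gene chromosome.
#' @param gene_length_range bp, uniform.
#' @param intergenic_gap_range bp between transcription units, uniform.
#' @param neighbour_frac fraction of genes deliberately placed in divergent
#'   promoter pairs (TSSs \code{neighbour_gap} apart) that the 5 kb
#'   neighbour rule must remove.
#' @param neighbour_gap bp between the TSSs of a planted divergent pair.
#' @param low_expr_frac fraction of (non-paired) genes planted below the
#'   TPM filter.
#' @param expr_meanlog,expr_sdlog,expr_min lognormal body rate (coverage
#'   depth units), floored at \code{expr_min}.
#' @param low_expr_rate body rate of planted low-expression genes
#'   (default 0: transcriptionally silent, so the TPM filter's planted set
#'   is recovered exactly at any cohort size).
#' @param readthrough list: \code{r_control}, \code{r_depleted} (fraction of
#'   body rate continuing past the TES), \code{affected_frac} (genes whose r
#'   rises on depletion), \code{decay_bp} (exponential tail decay length).
#' @param prompt list: \code{q} (antisense rate as a fraction of the body
#'   rate), \code{extent_control}, \code{extent_depleted} (bp; hard-stop
#'   plateau), \code{affected_frac} (genes whose extent lengthens).
#' @param upstream_contam list: \code{n} genes, \code{rate_frac} (sense
#'   upstream rate as a fraction of body rate, depleted condition only).
#' @param se list: \code{n_regions}, \code{width_range}, \code{gap},
#'   \code{amp_control} (per-strand units), \code{fold_depleted},
#'   \code{max_units} (per-region multiplier drawn from 1..max_units).
#' @param pas list: \code{n_up}, \code{n_stable} — candidate planted AWTAAA
#'   counts for PROMPT windows of prompt-affected (upregulated) versus
#'   stable genes.
#' @param noise apply per-base Poisson sampling.
#' @param read_length bp of emitted reads (read emitter for counting).
#' @param proteomics list: \code{n_proteins}, \code{n_depleted},
#'   \code{n_contaminants}, \code{null_sd}, \code{depleted_range},
#'   \code{n_ratios}, \code{pep_fail_frac} (fraction of depleted proteins
#'   planted below the peptide gate).
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 200L,
                           gene_length_range = c(2000L, 6000L),
                           intergenic_gap_range = c(18000L, 25000L),
                           neighbour_frac = 0.2,
                           neighbour_gap = 2000L,
                           low_expr_frac = 0.1,
                           expr_meanlog = log(150),
                           expr_sdlog = 0.5,
                           expr_min = 50,
                           low_expr_rate = 0,
                           readthrough = list(r_control = 0.05,
                                              r_depleted = 0.4,
                                              affected_frac = 0.5,
                                              decay_bp = 500L),
                           prompt = list(q = 0.15,
                                         extent_control = 1500L,
                                         extent_depleted = 8000L,
                                         affected_frac = 0.5),
                           upstream_contam = list(n = 5L, rate_frac = 0.5),
                           se = list(n_regions = 111L,
                                     width_range = c(3000L, 6000L),
                                     gap = 9000L,
                                     amp_control = 20,
                                     fold_depleted = 3,
                                     max_units = 3L),
                           pas = list(n_up = 0:2, n_stable = 4:8),
                           noise = TRUE,
                           read_length = 100L,
                           proteomics = list(n_proteins = 200L,
                                             n_depleted = 4L,
                                             n_contaminants = 2L,
                                             null_sd = 0.08,
                                             depleted_range = c(0.3, 0.6),
                                             n_ratios = 3L,
                                             pep_fail_frac = 0.25)) {
  spec <- as.list(environment())
  stopifnot(spec$n_genes >= 1,
            spec$readthrough$r_control >= 0,
            spec$readthrough$r_control <= 1,
            spec$readthrough$r_depleted >= 0,
            spec$readthrough$r_depleted <= 1,
            spec$prompt$q >= 0,
            spec$se$amp_control >= 0,
            spec$proteomics$n_depleted <= spec$proteomics$n_proteins)
  structure(spec, class = "synthetic_spec")
}

#' Reduced-scale spec for the demo pipeline
#' @param seed master seed.
#' @return \code{synthetic_spec} with fewer genes, super-enhancers and
#'   proteins (same rates and effect sizes as the default).
#' @export
demo_spec <- function(seed = 1L) {
  synthetic_spec(seed = seed, n_genes = 40L,
                 se = list(n_regions = 20L, width_range = c(3000L, 6000L),
                           gap = 9000L, amp_control = 20, fold_depleted = 3,
                           max_units = 3L),
                 proteomics = list(n_proteins = 100L, n_depleted = 3L,
                                   n_contaminants = 2L, null_sd = 0.08,
                                   depleted_range = c(0.3, 0.6),
                                   n_ratios = 3L, pep_fail_frac = 0.25))
}

.runif_int <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

# random exon structure: 1-3 exons within [start, end)
.random_exons <- function(start, end) {
  len <- end - start
  k <- sample.int(3L, 1L)
  if (k == 1L || len < 600L) {
    return(data.frame(start = start, end = end))
  }
  nseg <- 2L * k - 1L
  cuts <- sort(sample(seq(100L, len - 100L, by = 50L), nseg - 1L))
  bounds <- c(0L, cuts, len)
  seg_start <- start + bounds[-length(bounds)]
  seg_end <- start + bounds[-1]
  odd <- seq(1L, nseg, by = 2L)
  data.frame(start = seg_start[odd], end = seg_end[odd])
}

#' Generate the synthetic annotation and per-gene truth table
#'
#' Places transcription units along a gene chromosome with intergenic gaps
#' wide enough that only the deliberately planted divergent pairs violate
#' the 5 kb neighbour rule, assigns body rates and effect classes, and lays
#' out super-enhancer regions on a second chromosome.
#'
#' @param spec [synthetic_spec()].
#' @return list: \code{genes} (gene models), \code{truth} (per-gene truth
#'   data.frame), \code{chrom_lengths}, \code{se_regions} (interval table
#'   with names), \code{se_truth}.
#' @export
make_annotation <- function(spec) {
  .with_seed(spec$seed + 13L, {
    n <- spec$n_genes
    n_pairs <- floor(n * spec$neighbour_frac / 2)
    n_single <- n - 2L * n_pairs
    # interleave pair units evenly among singleton units
    unit_is_pair <- rep(FALSE, n_single + n_pairs)
    if (n_pairs > 0) {
      at <- unique(pmin(n_single + n_pairs,
                        floor(seq(2, n_single + n_pairs,
                                  length.out = n_pairs))))
      unit_is_pair[at] <- TRUE
      while (sum(unit_is_pair) < n_pairs) {
        unit_is_pair[which(!unit_is_pair)[1]] <- TRUE
      }
    }
    cursor <- 12000L
    rows <- list()
    gi <- 0L
    for (u in seq_along(unit_is_pair)) {
      gap <- .runif_int(1, spec$intergenic_gap_range)
      s <- cursor + gap
      if (unit_is_pair[u]) {
        lenB <- .runif_int(1, spec$gene_length_range)
        lenA <- .runif_int(1, spec$gene_length_range)
        gi <- gi + 1L
        rows[[length(rows) + 1L]] <-
          list(gene_id = sprintf("gene_%04d", gi), start = s,
               end = s + lenB, strand = "-", neighboured = TRUE)
        a0 <- s + lenB + spec$neighbour_gap
        gi <- gi + 1L
        rows[[length(rows) + 1L]] <-
          list(gene_id = sprintf("gene_%04d", gi), start = a0,
               end = a0 + lenA, strand = "+", neighboured = TRUE)
        cursor <- a0 + lenA
      } else {
        len <- .runif_int(1, spec$gene_length_range)
        gi <- gi + 1L
        rows[[length(rows) + 1L]] <-
          list(gene_id = sprintf("gene_%04d", gi), start = s,
               end = s + len, strand = sample(c("+", "-"), 1),
               neighboured = FALSE)
        cursor <- s + len
      }
    }
    chr_len <- cursor + 15000L
    truth <- data.frame(
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      chrom = "chr1",
      start = vapply(rows, function(r) as.numeric(r$start), 0),
      end = vapply(rows, function(r) as.numeric(r$end), 0),
      strand = vapply(rows, `[[`, "", "strand"),
      is_neighboured = vapply(rows, `[[`, TRUE, "neighboured"),
      stringsAsFactors = FALSE)
    eligible <- !truth$is_neighboured
    n_low <- floor(n * spec$low_expr_frac)
    truth$is_low <- FALSE
    truth$is_low[sample(which(eligible), min(n_low, sum(eligible)))] <- TRUE
    cohort <- eligible & !truth$is_low
    truth$lambda <- ifelse(
      truth$is_low, spec$low_expr_rate,
      pmax(spec$expr_min, stats::rlnorm(n, spec$expr_meanlog,
                                        spec$expr_sdlog)))
    pick <- function(frac) {
      out <- rep(FALSE, n)
      idx <- which(cohort)
      out[sample(idx, round(length(idx) * frac))] <- TRUE
      out
    }
    truth$rt_affected <- pick(spec$readthrough$affected_frac)
    truth$prompt_affected <- pick(spec$prompt$affected_frac)
    truth$upstream_contam <- FALSE
    truth$upstream_contam[sample(which(cohort),
                                 min(spec$upstream_contam$n,
                                     sum(cohort)))] <- TRUE
    truth$in_cohort <- cohort
    truth$r_control <- spec$readthrough$r_control
    truth$r_depleted <- ifelse(truth$rt_affected,
                               spec$readthrough$r_depleted,
                               spec$readthrough$r_control)
    truth$extent_control <- spec$prompt$extent_control
    truth$extent_depleted <- ifelse(truth$prompt_affected,
                                    spec$prompt$extent_depleted,
                                    spec$prompt$extent_control)
    genes <- gene_models(gene_id = truth$gene_id, chrom = truth$chrom,
                         start = truth$start, end = truth$end,
                         strand = truth$strand,
                         exons = lapply(seq_len(n), function(i) {
                           .random_exons(truth$start[i], truth$end[i])
                         }))
    truth$exonic_length <- exonic_length(genes)
    # super-enhancer chromosome
    nse <- spec$se$n_regions
    widths <- .runif_int(nse, spec$se$width_range)
    gaps <- rep(spec$se$gap, nse)
    se_start <- 5000L + cumsum(c(0L, (widths + gaps)[-nse]))
    se_end <- se_start + widths
    units <- sample.int(spec$se$max_units, nse, replace = TRUE)
    se_regions <- genomic_intervals("chrSE", se_start, se_end, "*")
    se_regions$name <- sprintf("SE_%03d", seq_len(nse))
    se_truth <- data.frame(
      name = se_regions$name, start = se_start, end = se_end,
      units = units,
      amp_control = spec$se$amp_control * units,
      amp_depleted = spec$se$amp_control * units * spec$se$fold_depleted,
      stringsAsFactors = FALSE)
    chrom_lengths <- c(chr1 = chr_len,
                       chrSE = se_end[nse] + spec$se$gap)
    list(genes = genes, truth = truth, chrom_lengths = chrom_lengths,
         se_regions = se_regions, se_truth = se_truth)
  })
}

# generate a random sequence of length n with no AWTAAA on the given strand
# orientation (vector of single characters)
.motif_free <- function(n) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  repeat {
    hits <- scan_pas(paste(s, collapse = ""))
    if (!length(hits)) return(s)
    for (h in hits) {
      s[(h + 1):(h + 6)] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    }
  }
}

#' Generate the synthetic genome with planted PAS motifs
#'
#' Random sequence everywhere except the PROMPT windows of cohort genes,
#' which are made AWTAAA-free (in transcript orientation) and then seeded
#' with a recorded number of planted AATAAA/ATTAAA motifs at recorded
#' offsets. The planting manifest lists every site.
#'
#' @param spec [synthetic_spec()].
#' @param ann output of [make_annotation()].
#' @param prompt_window_bp window length the analysis will scan (default
#'   3000, matching [analysis_params()]).
#' @return list: \code{genome} (\code{DNAStringSet}), \code{pas_manifest}
#'   (data.frame: prompt_id, parent_gene, class, n_planted, offsets).
#' @export
make_genome <- function(spec, ann, prompt_window_bp = 3000L) {
  .with_seed(spec$seed + 11L, {
    seqs <- lapply(ann$chrom_lengths, function(len) {
      sample(c("A", "C", "G", "T"), len, replace = TRUE)
    })
    cohort_genes <- ann$genes[ann$truth$in_cohort, , drop = FALSE]
    windows <- suppressWarnings(
      define_prompt_windows(cohort_genes, prompt_window_bp,
                            ann$chrom_lengths))
    up_class <- ann$truth$prompt_affected[match(windows$parent_gene,
                                                ann$truth$gene_id)]
    manifest <- vector("list", nrow(windows))
    for (i in seq_len(nrow(windows))) {
      L <- windows$end[i] - windows$start[i]
      n_sites <- if (up_class[i]) sample(spec$pas$n_up, 1)
                 else sample(spec$pas$n_stable, 1)
      if (L < 6 * (n_sites + 1)) stop("PROMPT window too small for planting")
      for (try in 1:100) {
        s <- .motif_free(L)
        offs <- sort(sample.int(L - 6L, n_sites))
        if (n_sites > 1 && any(diff(offs) < 6L)) next
        for (o in offs) {
          motif <- sample(c("AATAAA", "ATTAAA"), 1)
          s[(o + 1):(o + 6)] <- strsplit(motif, "")[[1]]
        }
        found <- scan_pas(paste(s, collapse = ""))
        if (identical(as.integer(found), as.integer(offs))) break
        if (try == 100) stop("failed to plant PAS motifs")
      }
      # place back in genomic orientation
      if (windows$strand[i] == "-") {
        g <- rev(chartr("ACGT", "TGCA", s))
      } else {
        g <- s
      }
      seqs[[windows$chrom[i]]][(windows$start[i] + 1):windows$end[i]] <- g
      manifest[[i]] <- data.frame(
        prompt_id = windows$prompt_id[i],
        parent_gene = windows$parent_gene[i],
        class = if (up_class[i]) "upregulated" else "stable",
        n_planted = n_sites,
        offsets = paste(offs, collapse = ","),
        stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(
      vapply(seqs, paste, "", collapse = ""))
    names(genome) <- names(ann$chrom_lengths)
    list(genome = genome, pas_manifest = do.call(rbind, manifest))
  })
}

# expected (noise-free) coverage for one condition; returns stranded_coverage
.expected_coverage <- function(spec, ann, condition) {
  cov <- stranded_coverage(ann$chrom_lengths, 1L)
  tr <- ann$truth
  dep <- condition == "depleted"
  decay <- spec$readthrough$decay_bp
  tail_len <- 6L * decay
  plus <- cov$plus$chr1
  minus <- cov$minus$chr1
  len1 <- ann$chrom_lengths[["chr1"]]
  for (i in seq_len(nrow(tr))) {
    lam <- tr$lambda[i]
    st <- tr$start[i]; en <- tr$end[i]
    sense_plus <- tr$strand[i] == "+"
    body <- (st + 1):en
    if (sense_plus) plus[body] <- plus[body] + lam
    else minus[body] <- minus[body] + lam
    r <- if (dep) tr$r_depleted[i] else tr$r_control[i]
    if (r > 0) {
      if (sense_plus) {
        tl <- min(tail_len, len1 - en)
        if (tl > 0) {
          idx <- (en + 1):(en + tl)
          plus[idx] <- plus[idx] + lam * r * exp(-(seq_len(tl) - 1) / decay)
        }
      } else {
        tl <- min(tail_len, st)
        if (tl > 0) {
          idx <- st:(st - tl + 1)
          minus[idx] <- minus[idx] + lam * r * exp(-(seq_len(tl) - 1) / decay)
        }
      }
    }
    if (tr$in_cohort[i]) {
      E <- if (dep) tr$extent_depleted[i] else tr$extent_control[i]
      if (sense_plus) {
        E <- min(E, st)
        if (E > 0) {
          idx <- (st - E + 1):st
          minus[idx] <- minus[idx] + lam * spec$prompt$q
        }
      } else {
        E <- min(E, len1 - en)
        if (E > 0) {
          idx <- (en + 1):(en + E)
          plus[idx] <- plus[idx] + lam * spec$prompt$q
        }
      }
    }
    if (dep && tr$upstream_contam[i]) {
      w <- 1000L
      if (sense_plus) {
        idx <- (st - w + 1):st
        plus[idx] <- plus[idx] + lam * spec$upstream_contam$rate_frac
      } else {
        idx <- (en + 1):(en + w)
        minus[idx] <- minus[idx] + lam * spec$upstream_contam$rate_frac
      }
    }
  }
  cov$plus$chr1 <- plus
  cov$minus$chr1 <- minus
  amp <- if (dep) ann$se_truth$amp_depleted else ann$se_truth$amp_control
  for (j in seq_len(nrow(ann$se_truth))) {
    idx <- (ann$se_truth$start[j] + 1):ann$se_truth$end[j]
    cov$plus$chrSE[idx] <- cov$plus$chrSE[idx] + amp[j]
    cov$minus$chrSE[idx] <- cov$minus$chrSE[idx] + amp[j]
  }
  cov
}

#' Simulate a stranded coverage track for one condition
#'
#' Deterministic expected coverage (gene bodies, decaying post-TES tails,
#' hard-stop antisense PROMPT plateaus, bidirectional super-enhancer
#' plateaus, upstream contamination) with optional per-base Poisson
#' sampling, seeded per (condition, replicate).
#'
#' @param spec [synthetic_spec()].
#' @param ann output of [make_annotation()].
#' @param condition \code{"control"} or \code{"depleted"}.
#' @param replicate replicate index (enters the child seed).
#' @param noise override \code{spec$noise}.
#' @return \code{stranded_coverage} (bin size 1).
#' @export
simulate_coverage <- function(spec, ann,
                              condition = c("control", "depleted"),
                              replicate = 1L, noise = spec$noise) {
  condition <- match.arg(condition)
  cov <- .expected_coverage(spec, ann, condition)
  if (!noise) return(cov)
  offset <- if (condition == "control") 100L else 200L
  .with_seed(spec$seed + offset + replicate, {
    for (slot in c("plus", "minus")) {
      cov[[slot]] <- lapply(cov[[slot]], function(v) {
        out <- v
        nz <- v > 0
        out[nz] <- stats::rpois(sum(nz), v[nz])
        out
      })
    }
    cov
  })
}

#' Emit synthetic stranded reads over gene bodies
#'
#' Read-interval emitter for exercising pileup and exonic counting: each
#' gene emits \code{Poisson(lambda * length / read_length)} reads of fixed
#' length, uniformly placed in its span, on its own strand.
#'
#' @param spec [synthetic_spec()].
#' @param ann output of [make_annotation()].
#' @return interval table of reads.
#' @export
simulate_reads <- function(spec, ann) {
  .with_seed(spec$seed + 31L, {
    tr <- ann$truth
    rl <- spec$read_length
    parts <- lapply(seq_len(nrow(tr)), function(i) {
      n <- stats::rpois(1, tr$lambda[i] * (tr$end[i] - tr$start[i]) / rl)
      if (n == 0) return(NULL)
      st <- floor(stats::runif(n, tr$start[i], tr$end[i] - rl))
      data.frame(chrom = tr$chrom[i], start = st, end = st + rl,
                 strand = tr$strand[i], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Filter(Negate(is.null), parts))
    class(out) <- c("genomic_intervals", "data.frame")
    out
  })
}

#' Simulate a two-condition counts matrix with planted fold changes
#'
#' Per-gene base means are lognormal; a planted subset is multiplied by
#' \code{fold} in the condition samples; per-sample depth factors are
#' uniform; observed counts are Poisson.
#'
#' @param n_genes number of genes.
#' @param reps_ctrl,reps_cond replicates per condition.
#' @param base_meanlog,base_sdlog lognormal base mean parameters.
#' @param n_planted genes with a true fold change.
#' @param fold true fold change of planted genes (condition vs control).
#' @param depth_range per-sample depth factor range.
#' @param seed RNG seed.
#' @return list: \code{counts_ctrl}, \code{counts_cond} (matrices with
#'   gene_id rownames), \code{planted} (logical vector).
#' @export
simulate_counts <- function(n_genes = 2000L, reps_ctrl = 3L, reps_cond = 3L,
                            base_meanlog = log(200), base_sdlog = 1,
                            n_planted = 0L, fold = 1,
                            depth_range = c(0.8, 1.25), seed = 1L) {
  .with_seed(seed, {
    mu <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    planted <- rep(FALSE, n_genes)
    if (n_planted > 0) planted[sample.int(n_genes, n_planted)] <- TRUE
    sf <- stats::runif(reps_ctrl + reps_cond, depth_range[1], depth_range[2])
    gid <- sprintf("gene_%05d", seq_len(n_genes))
    draw <- function(j, cond) {
      m <- mu * sf[j] * ifelse(cond & planted, fold, 1)
      stats::rpois(n_genes, m)
    }
    counts_ctrl <- vapply(seq_len(reps_ctrl), function(j) draw(j, FALSE),
                          numeric(n_genes))
    counts_cond <- vapply(seq_len(reps_cond),
                          function(j) draw(reps_ctrl + j, TRUE),
                          numeric(n_genes))
    dimnames(counts_ctrl) <- list(gid, sprintf("ctrl_%d", seq_len(reps_ctrl)))
    dimnames(counts_cond) <- list(gid, sprintf("cond_%d", seq_len(reps_cond)))
    list(counts_ctrl = counts_ctrl, counts_cond = counts_cond,
         planted = stats::setNames(planted, gid))
  })
}

#' Simulate a proximity-labelling quantification table
#'
#' Null proteins draw replicate ratios from Normal(1, null_sd) truncated at
#' zero; planted depleted proteins draw from Uniform(depleted_range).
#' Contaminant proteins carry depleted-like ratios so the contaminant list
#' is load-bearing. A configurable fraction of depleted proteins is planted
#' below the peptide gate to exercise that gate.
#'
#' @param spec [synthetic_spec()].
#' @return list: \code{table} (data.frame: protein_id, peptide_count,
#'   ratio_rep columns), \code{truth} (protein_id, depleted,
#'   fails_peptide_gate, contaminant), \code{contaminants} (identifiers).
#' @export
simulate_proteomics <- function(spec) {
  pr <- spec$proteomics
  .with_seed(spec$seed + 41L, {
    n <- pr$n_proteins
    ids <- sprintf("PROT_%04d", seq_len(n))
    depleted <- rep(FALSE, n)
    depleted[sample.int(n, pr$n_depleted)] <- TRUE
    contaminant <- rep(FALSE, n)
    pool <- which(!depleted)
    contaminant[sample(pool, min(pr$n_contaminants, length(pool)))] <- TRUE
    fails <- depleted & stats::runif(n) < pr$pep_fail_frac
    peptides <- integer(n)
    peptides[!depleted] <- sample(2:30, sum(!depleted), replace = TRUE)
    peptides[depleted & !fails] <- sample(6:30, sum(depleted & !fails),
                                          replace = TRUE)
    peptides[fails] <- sample(1:4, sum(fails), replace = TRUE)
    ratios <- matrix(0, n, pr$n_ratios)
    low <- depleted | contaminant
    ratios[!low, ] <- pmax(0, stats::rnorm(sum(!low) * pr$n_ratios, 1,
                                           pr$null_sd))
    ratios[low, ] <- stats::runif(sum(low) * pr$n_ratios,
                                  pr$depleted_range[1], pr$depleted_range[2])
    tab <- data.frame(protein_id = ids, peptide_count = peptides,
                      stringsAsFactors = FALSE)
    for (j in seq_len(pr$n_ratios)) {
      tab[[sprintf("ratio_rep%d", j)]] <- round(ratios[, j], 4)
    }
    truth <- data.frame(protein_id = ids, depleted = depleted,
                        fails_peptide_gate = fails,
                        contaminant = contaminant, stringsAsFactors = FALSE)
    list(table = tab, truth = truth, contaminants = ids[contaminant])
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits genome.fa, annotation.gtf, chrom.sizes, se_regions.bed, per-
#' condition bedGraph pairs, proteomics.tsv, a contaminants list and
#' machine-readable truth tables under \code{truth/}. Byte-identical for a
#' fixed spec.
#'
#' @param spec [synthetic_spec()].
#' @param dir output directory (created).
#' @return invisibly, a list with the in-memory objects (\code{ann},
#'   \code{genome}, \code{pas_manifest}, \code{cov_ctrl}, \code{cov_dep},
#'   \code{proteomics}) and \code{dir}.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ann <- make_annotation(spec)
  gen <- make_genome(spec, ann)
  cov_ctrl <- simulate_coverage(spec, ann, "control")
  cov_dep <- simulate_coverage(spec, ann, "depleted")
  prot <- simulate_proteomics(spec)
  Biostrings::writeXStringSet(gen$genome, file.path(dir, "genome.fa"))
  write_gtf(ann$genes, file.path(dir, "annotation.gtf"))
  write_chrom_sizes(ann$chrom_lengths, file.path(dir, "chrom.sizes"))
  write_bed(ann$se_regions, file.path(dir, "se_regions.bed"))
  write_bedgraph(cov_ctrl, file.path(dir, "control.rep1"))
  write_bedgraph(cov_dep, file.path(dir, "depleted.rep1"))
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(prot$table, "proteomics.tsv")
  writeLines(prot$contaminants, file.path(dir, "contaminants.txt"))
  wt(ann$truth, "truth/genes.tsv")
  wt(ann$se_truth, "truth/se.tsv")
  wt(gen$pas_manifest, "truth/pas_manifest.tsv")
  wt(prot$truth, "truth/proteomics.tsv")
  invisible(list(spec = spec, ann = ann, genome = gen$genome,
                 pas_manifest = gen$pas_manifest, cov_ctrl = cov_ctrl,
                 cov_dep = cov_dep, proteomics = prot, dir = dir))
}
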
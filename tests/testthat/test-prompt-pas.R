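test_that("PROMPT windows sit upstream and antisense of their parent", {
  g <- gene_models(c("a", "b"), "chr1", c(10000, 10000), c(20000, 20000),
                   c("+", "-"))
  # construct separately (together their windows overlap the other gene)
  wa <- define_prompt_windows(g[1, , drop = FALSE], 3000)
  expect_equal(wa$start, 7000)
  expect_equal(wa$end, 10000)
  expect_equal(wa$strand, "-")
  gb <- g[2, , drop = FALSE]
  class(gb) <- class(g)
  wb <- define_prompt_windows(gb, 3000)
  expect_equal(wb$start, 20000)
  expect_equal(wb$end, 23000)
  expect_equal(wb$strand, "+")
  # clipping at the chromosome start
  gc_ <- gene_models("c", "chr1", 1000, 6000, "+")
  wc <- define_prompt_windows(gc_, 3000)
  expect_equal(wc$start, 0)
  expect_equal(wc$end, 1000)
})

test_that("PROMPT windows never intersect their parent gene body", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 10
    start <- sort(sample.int(500000L, n)) + seq(0, by = 20000, length.out = n)
    g <- gene_models(sprintf("g%02d", 1:n), "chr1", start, start + 3000,
                     sample(c("+", "-"), n, TRUE))
    w <- suppressWarnings(define_prompt_windows(g, 3000))
    for (i in seq_len(nrow(w))) {
      parent <- g[g$gene_id == w$parent_gene[i], ]
      expect_false(w$start[i] < parent$end && w$end[i] > parent$start)
      expect_true(w$strand[i] != parent$strand)
    }
  }
})

test_that("windows overlapping another gene are dropped with a warning", {
  g <- gene_models(c("a", "b"), "chr1", c(10000, 8000), c(20000, 9500),
                   c("+", "+"))
  expect_warning(w <- define_prompt_windows(g, 3000), "dropped")
  expect_false("a_PROMPT" %in% w$prompt_id)
})

test_that("the AWTAAA scan reports all overlapping hexamers, never N", {
  expect_equal(scan_pas("AATAAA"), 0L)
  expect_equal(scan_pas("ATTAAA"), 0L)
  expect_equal(scan_pas("AATAAATTAAA"), c(0L, 5L))
  expect_equal(scan_pas("AGTAAA"), integer(0))
  expect_equal(scan_pas("ANTAAA"), integer(0))
  expect_equal(scan_pas("AATAA"), integer(0))
  expect_equal(scan_pas("aataaa"), 0L)
})

test_that("the motif scan matches the exhaustive 6-mer oracle", {
  set.seed(37)
  for (i in 1:1000) {
    # AT-rich alphabet with occasional N so matches are common
    s <- paste(sample(c("A", "C", "G", "T", "T", "A", "N"), 1000,
                      replace = TRUE), collapse = "")
    expect_identical(scan_pas(s), as.integer(oracle_scan_pas(s)))
  }
})

test_that("PAS density uses transcript orientation and realised length", {
  # 2000 bp minus-strand window with 3 planted motifs; the genomic plus
  # strand carries their reverse complements
  tx <- rep("C", 2000)
  for (o in c(100, 700, 1500)) tx[(o + 1):(o + 6)] <-
      strsplit("AATAAA", "")[[1]]
  genomic <- rev(chartr("ACGT", "TGCA", tx))
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(genomic, collapse = "")))
  prompts <- data.frame(prompt_id = "p1", parent_gene = "g1", chrom = "chr1",
                        start = 0, end = 2000, strand = "-")
  d <- pas_density(prompts, genome)
  expect_equal(d$n_sites, 3)
  expect_equal(d$density_per_kb, 1.5)
  expect_equal(d$positions[[1]], c(100L, 700L, 1500L))
  # motif-free sequence scores zero
  genome0 <- Biostrings::DNAStringSet(c(chr1 = strrep("CG", 1000)))
  expect_equal(pas_density(prompts, genome0)$n_sites, 0)
  expect_error(pas_density(data.frame(prompt_id = "p", parent_gene = "g",
                                      chrom = "chrX", start = 0, end = 10,
                                      strand = "+"), genome),
               "chrX")
})

test_that("PROMPT fold changes use the inclusive log2FC >= 1 rule", {
  cl <- c(chr1 = 40000)
  g <- gene_models("a", "chr1", 10000, 20000, "+")
  w <- define_prompt_windows(g, 3000)
  ctrl <- stranded_coverage(cl)
  ctrl$minus$chr1[7001:10000] <- 4
  same <- prompt_fc(w, ctrl, ctrl)
  expect_equal(same$log2fc, 0)
  expect_false(same$upregulated)
  # condition level chosen so (cond + p)/(ctrl + p) is exactly 2:
  # log2fc == 1.0 must be classed upregulated (inclusive threshold)
  cond <- stranded_coverage(cl)
  cond$minus$chr1[7001:10000] <- 2 * (4 + 0.01) - 0.01
  fc <- prompt_fc(w, ctrl, cond)
  expect_equal(fc$log2fc, 1.0)
  expect_true(fc$upregulated)
})

test_that("density classes partition the catalogue exhaustively", {
  dens <- data.frame(prompt_id = c("a_PROMPT", "b_PROMPT", "c_PROMPT"),
                     length_bp = 3000, n_sites = c(0, 4, 6),
                     density_per_kb = c(0, 4, 6) / 3)
  prompts <- data.frame(prompt_id = dens$prompt_id,
                        upregulated = c(TRUE, FALSE, FALSE))
  sp <- split_density_by_class(dens, prompts)
  expect_equal(sum(sp$summary$n), 3)
  expect_equal(sp$summary$n, c(1, 2))
  expect_equal(sp$summary$median_density, c(0, 5 / 3))
  # empty group handled
  all_up <- prompts
  all_up$upregulated <- TRUE
  sp2 <- split_density_by_class(dens, all_up)
  expect_equal(sp2$summary$n, c(3, 0))
  expect_true(is.na(sp2$summary$median_density[2]))
})

test_that("the extent estimator finds a planted hard-stop plateau", {
  cl <- c(chr1 = 60000)
  for (strand in c("+", "-")) {
    g <- if (strand == "+") gene_models("g", "chr1", 30000, 35000, "+")
         else gene_models("g", "chr1", 25000, 30000, "-")
    cov <- stranded_coverage(cl)
    E <- 4200
    if (strand == "+") cov$minus$chr1[(30000 - E + 1):30000] <- 10
    else cov$plus$chr1[30001:(30000 + E)] <- 10
    expect_equal(estimate_prompt_extent(cov, g, max_extent = 10000,
                                        bin = 50), E)
  }
})
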
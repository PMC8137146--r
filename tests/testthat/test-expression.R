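test_that("exonic counting is per-gene unique and strand-aware", {
  g <- gene_models("g1", "chr1", 1000, 5000, "+",
                   exons = list(data.frame(start = c(1000, 3000),
                                           end = c(2000, 4000))))
  inside <- genomic_intervals("chr1", 1100, 1200, "+")
  expect_equal(count_exonic(inside, g), 1L)
  # a read bridging the intron and touching both exons counts once
  bridge <- genomic_intervals("chr1", 1900, 3100, "+")
  expect_equal(count_exonic(bridge, g), 1L)
  # intronic and antisense reads never count
  intron <- genomic_intervals("chr1", 2200, 2400, "+")
  anti <- genomic_intervals("chr1", 1100, 1200, "-")
  expect_equal(count_exonic(intron, g), 0L)
  expect_equal(count_exonic(anti, g), 0L)
})

test_that("exonic counting matches the all-pairs oracle", {
  set.seed(61)
  n_genes <- 20
  start <- sort(sample.int(180000L, n_genes))
  genes <- gene_models(sprintf("g%02d", 1:n_genes), "chr1", start,
                       start + sample(2000:4000, n_genes, TRUE),
                       sample(c("+", "-"), n_genes, TRUE),
                       exons = lapply(1:n_genes, function(i) {
                         data.frame(start = start[i] + c(0, 1200),
                                    end = start[i] + c(600, 1800))
                       }))
  rs <- sample.int(200000L, 500) - 1L
  reads <- genomic_intervals("chr1", rs, rs + 100L,
                             sample(c("+", "-"), 500, TRUE))
  got <- count_exonic_all(reads, genes)
  for (i in 1:n_genes) {
    expect_equal(unname(got[i]),
                 oracle_count_exonic(reads, genes[i, , drop = FALSE]))
  }
})

test_that("TPM is length-normalised and sums to one million", {
  expect_equal(compute_tpm(c(10, 30), c(1000, 3000)), c(5e5, 5e5))
  expect_equal(compute_tpm(c(7, 0), c(1500, 2000)), c(1e6, 0))
  expect_equal(compute_tpm(c(0, 0), c(1000, 1000)), c(0, 0))
  set.seed(71)
  counts <- rpois(300, 50)
  lens <- sample(500:8000, 300)
  tpm <- compute_tpm(counts, lens)
  expect_equal(sum(tpm), 1e6, tolerance = 1e-9)
  # ordering matches length-normalised rates
  expect_equal(order(tpm), order(counts / lens))
})

test_that("the TPM filter uses a strict lower bound", {
  expr <- data.frame(gene_id = c("a", "b", "c"), tpm = c(4.999, 5.0, 80))
  out <- filter_expressed(expr)
  expect_equal(out$low_expression, c(TRUE, FALSE, FALSE))
})

test_that("upstream read-through contamination flags only true gainers", {
  cl <- c(chr1 = 50000)
  g <- gene_models(c("a", "b"), "chr1", c(10000, 30000), c(15000, 35000),
                   c("+", "-"))
  ctrl <- constant_coverage(cl, 1.0)
  # identical tracks: ratio 1, nothing flagged
  same <- upstream_readthrough_filter(g, ctrl, ctrl)
  expect_false(any(same$contaminated))
  # 4x upstream gain on gene a only (its sense strand, upstream window)
  cond <- constant_coverage(cl, 1.0)
  cond$plus$chr1[9001:10000] <- 4.0
  out <- upstream_readthrough_filter(g, ctrl, cond)
  expect_equal(out$contaminated, c(TRUE, FALSE))
  expect_equal(out$log2fc[1], log2(4.01 / 1.01))
})

test_that("upregulation calls respect both the fold and FDR gates", {
  set.seed(81)
  # identical conditions: nothing called
  m <- matrix(rpois(600, 100), ncol = 3)
  rownames(m) <- sprintf("g%03d", 1:200)
  none <- call_upregulated(m, m)
  expect_false(any(none$upregulated))
  # a significant but sub-2-fold gene is rejected by the fold gate; the
  # null background keeps the size factors honest
  ctrl <- matrix(rpois(60 * 3, 10000), ncol = 3)
  cond <- matrix(rpois(60 * 3, 10000), ncol = 3)
  cond[60, ] <- rpois(3, 19000)  # ~1.9-fold, overwhelming evidence
  one <- call_upregulated(ctrl, cond)
  expect_lt(one$fdr[60], 1e-6)
  expect_gt(one$log2fc[60], 0.8)
  expect_false(any(one$upregulated))
  expect_error(call_upregulated(matrix(numeric(0), 5, 0), ctrl),
               "replicate")
})

test_that("single-replicate designs fall back to the exact Poisson test", {
  set.seed(91)
  ctrl <- cbind(c(rpois(50, 100), 100))
  cond <- cbind(c(rpois(50, 100), 480))
  out <- call_upregulated(ctrl, cond)
  expect_lt(out$fdr[51], 0.01)
  expect_true(out$upregulated[51])
  expect_false(any(out$upregulated[1:50]))
})
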
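# a small spec keeps generator tests fast; rates and effect sizes are the
# defaults
small_spec <- function(seed = 5, noise = TRUE) {
  synthetic_spec(seed = seed, n_genes = 24L, noise = noise,
                 se = list(n_regions = 8L, width_range = c(3000L, 6000L),
                           gap = 9000L, amp_control = 20, fold_depleted = 3,
                           max_units = 3L))
}

test_that("the generator is deterministic under its seed", {
  spec <- small_spec(11)
  a1 <- make_annotation(spec)
  a2 <- make_annotation(spec)
  expect_identical(a1, a2)
  g1 <- make_genome(spec, a1)
  g2 <- make_genome(spec, a2)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  c1 <- simulate_coverage(spec, a1, "depleted")
  c2 <- simulate_coverage(spec, a1, "depleted")
  expect_identical(c1, c2)
  # replicates draw different noise around the same expectation
  c3 <- simulate_coverage(spec, a1, "depleted", replicate = 2)
  expect_false(identical(c1$plus$chr1, c3$plus$chr1))
})

test_that("planted neighbour pairs are exactly what the 5 kb filter removes", {
  for (seed in c(2, 12)) {
    spec <- small_spec(seed)
    ann <- make_annotation(spec)
    kept <- filter_nonneighbouring(ann$genes)
    expect_setequal(kept$gene_id,
                    ann$truth$gene_id[!ann$truth$is_neighboured])
  }
})

test_that("noiseless coverage equals its analytic expectation", {
  spec <- small_spec(3, noise = FALSE)
  ann <- make_annotation(spec)
  cov <- simulate_coverage(spec, ann, "depleted")
  tr <- ann$truth
  i <- which(tr$in_cohort & tr$rt_affected)[1]
  g <- ann$genes[i, , drop = FALSE]
  # body mean is the planted rate exactly
  expect_equal(region_mean(cov, genomic_intervals(g$chrom, g$start, g$end,
                                                  g$strand), "sense"),
               tr$lambda[i], tolerance = 1e-9)
  # post-TES mean follows the geometric series of the decaying tail
  rec <- readthrough_record(cov, g)
  decay <- spec$readthrough$decay_bp
  w <- 1000
  expected_tail <- tr$lambda[i] * tr$r_depleted[i] *
    sum(exp(-(0:(w - 1)) / decay)) / w
  expect_equal(rec$post_tes_mean, expected_tail, tolerance = 1e-9)
  # total simulated signal is conserved (mass check over the chromosome)
  expect_true(all(cov$plus$chr1 >= 0) && all(is.finite(cov$plus$chr1)))
})

test_that("planted PAS sites are rediscovered exactly from the FASTA", {
  spec <- small_spec(7)
  ann <- make_annotation(spec)
  gen <- make_genome(spec, ann)
  cohort <- ann$genes[ann$truth$in_cohort, , drop = FALSE]
  class(cohort) <- class(ann$genes)
  w <- suppressWarnings(define_prompt_windows(cohort, 3000,
                                              ann$chrom_lengths))
  d <- pas_density(w, gen$genome)
  man <- gen$pas_manifest[match(d$prompt_id, gen$pas_manifest$prompt_id), ]
  expect_equal(d$n_sites, man$n_planted)
  got_offsets <- vapply(d$positions, paste, "", collapse = ",")
  expect_equal(got_offsets, man$offsets)
})

test_that("the read emitter supports counting and the TPM filter truth", {
  # a wider cohort so one stray read cannot lift a silent gene over TPM 5
  spec <- synthetic_spec(seed = 13, n_genes = 120L)
  ann <- make_annotation(spec)
  reads <- simulate_reads(spec, ann)
  expect_true(all(reads$end - reads$start == spec$read_length))
  counts <- count_exonic_all(reads, ann$genes)
  tpm <- compute_tpm(counts, exonic_length(ann$genes))
  expr <- filter_expressed(data.frame(gene_id = ann$genes$gene_id,
                                      tpm = tpm))
  # planted low-expression genes, and only those, fall below the threshold
  expect_setequal(expr$gene_id[expr$low_expression],
                  ann$truth$gene_id[ann$truth$is_low])
})

test_that("a written dataset is byte-identical under the same spec", {
  spec <- small_spec(21)
  d1 <- file.path(withr::local_tempdir(), "ds1")
  d2 <- file.path(withr::local_tempdir(), "ds2")
  simulate_dataset(spec, d1)
  simulate_dataset(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  m1 <- tools::md5sum(file.path(d1, f1))
  m2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(m1) == unname(m2)))
})
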
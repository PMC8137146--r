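test_that("a flat track yields a flat matrix and step tracks keep edges", {
  cl <- c(chr1 = 30000)
  cov <- constant_coverage(cl, 2.0)
  g <- gene_models("g", "chr1", 10000, 14000, "+")
  m <- build_matrix(cov, g, body_bins = 40, flank = 1000, bin_size = 10)
  expect_equal(dim(m$values), c(1, 240))
  expect_true(all(m$values == 2.0))
  expect_true(all(m$mask))
  # body 4, flanks 0
  cov2 <- stranded_coverage(cl)
  cov2$plus$chr1[10001:14000] <- 4
  m2 <- build_matrix(cov2, g, body_bins = 40, flank = 1000, bin_size = 10)
  expect_true(all(m2$values[1, 101:140] == 4))
  expect_true(all(m2$values[1, c(1:100, 141:240)] == 0))
})

test_that("minus-strand rows equal the manually reversed plus computation", {
  cl <- c(chr1 = 30000)
  set.seed(17)
  signal <- rpois(6000, 5)
  # plus gene carrying the signal on +, and a mirrored minus gene carrying
  # the reversed signal on - at mirrored coordinates
  covp <- stranded_coverage(cl)
  covp$plus$chr1[10001:16000] <- signal
  gp <- gene_models("g", "chr1", 11000, 15000, "+")
  covm <- stranded_coverage(cl)
  covm$minus$chr1[(30000 - 16000 + 1):(30000 - 10000)] <- rev(signal)
  gm <- gene_models("g", "chr1", 30000 - 15000, 30000 - 11000, "-")
  mp <- build_matrix(covp, gp, body_bins = 50, flank = 500, bin_size = 10)
  mm <- build_matrix(covm, gm, body_bins = 50, flank = 500, bin_size = 10)
  expect_equal(mm$values, mp$values)
})

test_that("row means collapse to region means at base resolution", {
  cl <- c(chr1 = 5000)
  set.seed(19)
  cov <- stranded_coverage(cl)
  cov$plus$chr1 <- rpois(5000, 2)
  g <- gene_models("g", "chr1", 1000, 1400, "+")
  m <- build_matrix(cov, g, body_bins = 400, flank = 0, bin_size = 1)
  expect_equal(mean(m$values[1, ]),
               region_mean(cov, genomic_intervals("chr1", 1000, 1400, "+")),
               tolerance = 1e-9)
})

test_that("profiles are permutation-invariant and strand-split", {
  cl <- c(chr1 = 100000)
  set.seed(23)
  start <- seq(10000, 80000, by = 10000)
  g <- gene_models(sprintf("g%d", seq_along(start)), "chr1", start,
                   start + 2000, rep(c("+", "-"), length.out = length(start)))
  cov <- stranded_coverage(cl)
  cov$plus$chr1 <- rpois(100000, 1)
  cov$minus$chr1 <- rpois(100000, 1)
  p1 <- strand_split_profile(cov, g, body_bins = 20, flank = 500,
                             bin_size = 50)
  perm <- sample(nrow(g))
  gp <- g[perm, , drop = FALSE]
  class(gp) <- class(g)
  p2 <- strand_split_profile(cov, gp, body_bins = 20, flank = 500,
                             bin_size = 50)
  expect_equal(p1$sense, p2$sense)
  expect_equal(p1$antisense, p2$antisense)

  # sense-only fixture: antisense profile is exactly zero
  cov0 <- stranded_coverage(cl)
  for (i in seq_len(nrow(g))) {
    idx <- (g$start[i] + 1):g$end[i]
    if (g$strand[i] == "+") cov0$plus$chr1[idx] <- 3
    else cov0$minus$chr1[idx] <- 3
  }
  p3 <- strand_split_profile(cov0, g, body_bins = 20, flank = 500,
                             bin_size = 50)
  expect_true(all(p3$antisense == 0))
  expect_true(all(p3$sense[p3$segment == "body"] == 3))

  # symmetric bidirectional fixture: antisense = -sense
  cov_bi <- constant_coverage(cl, 1.5)
  p4 <- strand_split_profile(cov_bi, g, body_bins = 20, flank = 500,
                             bin_size = 50)
  expect_equal(p4$antisense, -p4$sense)
})

test_that("SE metaplots recover log ratios with a reproducible halo", {
  cl <- c(chrSE = 120000)
  se <- genomic_intervals("chrSE", seq(5000, 95000, by = 10000),
                          seq(5000, 95000, by = 10000) + 4000)
  den <- constant_coverage(cl, 2.0)
  num4 <- constant_coverage(cl, 8.0)
  # identical tracks: all columns zero and the halo straddles zero
  ident <- se_metaplot(den, den, se, body_bins = 20, flank = 1000,
                       bin_size = 50, n_boot = 200, seed = 5)
  expect_true(all(ident$log2_ratio_mean == 0))
  expect_true(all(ident$ci_low <= 0 & ident$ci_high >= 0))
  # 4x numerator with a vanishing pseudocount: columns at 2
  four <- se_metaplot(num4, den, se, body_bins = 20, flank = 1000,
                      bin_size = 50, n_boot = 200, pseudocount = 1e-9,
                      seed = 5)
  expect_equal(four$log2_ratio_mean, rep(2, nrow(four)), tolerance = 1e-6)
  # same seed, same halo; different seed, different draw
  again <- se_metaplot(num4, den, se, body_bins = 20, flank = 1000,
                       bin_size = 50, n_boot = 200, pseudocount = 1e-9,
                       seed = 5)
  expect_identical(four$ci_low, again$ci_low)
  # fewer than two regions: mean only, with a warning
  expect_warning(
    one <- se_metaplot(num4, den, se[1, , drop = FALSE], body_bins = 20,
                       flank = 1000, bin_size = 50),
    "fewer than 2")
  expect_true(all(is.na(one$ci_low)))
})
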
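test_that("pileup adds one per overlapped bin on the read's own strand", {
  cl <- c(chr1 = 100)
  r <- genomic_intervals("chr1", 10, 20, "+")
  cov <- coverage_from_reads(r, cl)
  expect_equal(cov$plus$chr1[11:20], rep(1, 10))
  expect_equal(sum(cov$plus$chr1), 10)
  expect_equal(sum(cov$minus$chr1), 0)
  cov2 <- coverage_from_reads(rbind(r, r), cl)
  expect_equal(cov2$plus$chr1[11:20], rep(2, 10))
  expect_error(coverage_from_reads(genomic_intervals("chrX", 0, 5, "+"), cl),
               "unknown chromosome")
})

test_that("pileup of 1000 random reads matches the naive per-base oracle", {
  set.seed(31)
  cl <- c(chr1 = 5000)
  n <- 1000
  start <- sample.int(4900L, n, replace = TRUE) - 1L
  reads <- genomic_intervals("chr1", start,
                             start + sample.int(100L, n, replace = TRUE),
                             sample(c("+", "-"), n, TRUE))
  cov <- coverage_from_reads(reads, cl)
  expect_equal(cov$plus$chr1, oracle_pileup(reads, 5000, "+"))
  expect_equal(cov$minus$chr1, oracle_pileup(reads, 5000, "-"))
  # mass conservation at bin size 1
  expect_equal(sum(cov$plus$chr1) + sum(cov$minus$chr1),
               sum(reads$end - reads$start))
  expect_equal(cov$library_size, n)
})

test_that("RPKM scales by 1e9 / (library_size * bin_size)", {
  cl <- c(chr1 = 100000)
  cov <- stranded_coverage(cl, bin_size = 1000L)
  cov$plus$chr1[5] <- 1
  cov$library_size <- 1e6
  rp <- normalise_rpkm(cov)
  expect_equal(rp$plus$chr1[5], 1.0)
  expect_equal(rp$normalisation, "RPKM")
  # zeros stay zero, and normalising twice is an error
  expect_true(all(rp$plus$chr1[-5] == 0))
  expect_error(normalise_rpkm(rp), "already normalised")
  cov$library_size <- 0
  expect_error(normalise_rpkm(cov), "library_size")
  # total-signal identity on a random raw track
  set.seed(5)
  st <- sample.int(90000L, 200) - 1L
  r <- genomic_intervals("chr1", st, st + 150L, "+")
  raw <- coverage_from_reads(r, cl, bin_size = 10L)
  rpk <- normalise_rpkm(raw)
  expect_equal(sum(rpk$plus$chr1),
               sum(raw$plus$chr1) * 1e9 / (raw$library_size * 10))
})

test_that("region_mean resolves strands and averages bins", {
  cl <- c(chr1 = 1000)
  cov <- constant_coverage(cl, 2.0)
  reg <- genomic_intervals("chr1", 100, 300, "+")
  expect_equal(region_mean(cov, reg, "sense"), 2.0)
  expect_equal(region_mean(cov, reg, "both"), 4.0)
  cov2 <- stranded_coverage(cl)
  cov2$plus$chr1[101:200] <- 0
  cov2$plus$chr1[201:300] <- 4
  expect_equal(region_mean(cov2, reg, "sense"), 2.0)
  # antisense reads the opposite strand
  cov2$minus$chr1[101:300] <- 7
  expect_equal(region_mean(cov2, reg, "antisense"), 7.0)
  expect_error(region_mean(cov2, genomic_intervals("chr1", 2000, 3000, "+")),
               "outside chromosome")
})

test_that("region_mean matches per-base averaging on random queries", {
  set.seed(41)
  cl <- c(chr1 = 2000)
  cov <- stranded_coverage(cl)
  cov$plus$chr1 <- rpois(2000, 3)
  cov$minus$chr1 <- rpois(2000, 1)
  for (i in 1:100) {
    st <- sample.int(1990L, 1) - 1L
    en <- st + sample.int(2000L - st, 1)
    strand <- sample(c("+", "-"), 1)
    reg <- genomic_intervals("chr1", st, en, strand)
    v <- if (strand == "+") cov$plus$chr1 else cov$minus$chr1
    expect_equal(region_mean(cov, reg, "sense"), mean(v[(st + 1):en]))
  }
})

test_that("bedGraph round-trips are lossless and malformed input rejected", {
  cl <- c(chr1 = 3000, chr2 = 500)
  set.seed(13)
  cov <- stranded_coverage(cl)
  cov$plus$chr1 <- rpois(3000, 0.8)
  cov$minus$chr1 <- rpois(3000, 0.4)
  cov$minus$chr2 <- rpois(500, 2)
  prefix <- withr::local_tempfile()
  write_bedgraph(cov, prefix)
  back <- read_bedgraph(paste0(prefix, ".plus.bedgraph"),
                        paste0(prefix, ".minus.bedgraph"), cl)
  expect_equal(back$plus, cov$plus)
  expect_equal(back$minus, cov$minus)

  # empty files give an all-zero track
  e1 <- withr::local_tempfile(); e2 <- withr::local_tempfile()
  file.create(e1); file.create(e2)
  z <- read_bedgraph(e1, e2, cl)
  expect_true(all(z$plus$chr1 == 0) && all(z$minus$chr2 == 0))

  # hand-written records land in the right bins
  writeLines(c("chr1\t0\t10\t2.5", "chr1\t20\t25\t1", "chr2\t490\t500\t3"),
             e1)
  h <- read_bedgraph(e1, e2, cl)
  expect_equal(h$plus$chr1[1:10], rep(2.5, 10))
  expect_equal(h$plus$chr1[21:25], rep(1, 5))
  expect_equal(h$plus$chr2[491:500], rep(3, 10))
  expect_equal(sum(h$plus$chr1), 30)

  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), e1)
  expect_error(read_bedgraph(e1, e2, cl), "overlapping")
  writeLines("chr2\t400\t600\t1", e1)
  expect_error(read_bedgraph(e1, e2, cl), "beyond chromosome")
})
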
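sizes1 <- chrom_sizes(c(chr1 = 10000))

test_that("extend_reads extends directionally and clamps at boundaries", {
  sz <- sizes1
  reads <- genomic_intervals(rep("chr1", 3), c(100, 500, 50),
                             c(127, 527, 77), strand = c("+", "-", "-"))
  ext <- extend_reads(reads, 200, sz)
  expect_equal(ext$start, c(100, 327, 0))
  expect_equal(ext$end, c(300, 527, 77))
  expect_equal(nrow(ext), nrow(reads))
  expect_error(extend_reads(reads, 0, sz), "positive")
})

test_that("extend_reads treats strand '.' as '+' with a warning", {
  reads <- genomic_intervals("chr1", 100, 127, strand = ".")
  expect_warning(ext <- extend_reads(reads, 200, sizes1), "treated as")
  expect_equal(ext$end, 300)
})

test_that("unclamped extended reads have exactly the requested length", {
  withr::local_seed(11)
  sz <- toy_sizes(chr1 = 50000)
  reads <- random_reads(200, sz, max_len = 27)
  reads$start <- pmin(pmax(reads$start, 300), 49000)
  reads$end <- reads$start + 27
  ext <- extend_reads(reads, 200, sz)
  expect_true(all(ext$end - ext$start == 200))
})

test_that("bin_density reproduces the worked max-overlap example", {
  reads <- genomic_intervals(c("chr1", "chr1"), c(0, 100), c(200, 300),
                             strand = "+")
  tr <- bin_density(reads, 25, sizes1)
  v <- tr$values$chr1
  expect_equal(v[5], 2)    # bin [100,125): both reads overlap
  expect_equal(v[1], 1)    # bin [0,25)
  expect_equal(v[12], 1)   # bin [275,300)
  expect_equal(v[13], 0)
  single <- bin_density(genomic_intervals("chr1", 0, 200, strand = "+"),
                        25, sizes1)
  expect_equal(single$values$chr1[1:8], rep(1, 8))
  expect_equal(sum(single$values$chr1[-(1:8)]), 0)
})

test_that("bin_density of no reads is an all-zero track", {
  tr <- bin_density(genomic_intervals(), 25, sizes1)
  expect_equal(sum(tr$values$chr1), 0)
  expect_equal(tr$library_size, 0)
})

test_that("bin_density equals the brute-force per-base oracle", {
  withr::local_seed(123)
  for (i in 1:12) {
    sz <- toy_sizes(chrA = sample(2000:10000, 1),
                    chrB = sample(2000:10000, 1))
    reads <- random_reads(sample(50:500, 1), sz)
    for (bw in c(1, 7, 25)) {
      got <- bin_density(reads, bw, sz)$values
      expect_equal(got, brute_force_bins(reads, bw, sz),
                   info = sprintf("instance %d bw %d", i, bw))
    }
  }
})

test_that("normalize_to_input matches the pseudocount ratio formula", {
  chip <- make_track(c(20, 0, 5), library_size = 1e6)
  ctrl <- make_track(c(10, 0, 5), library_size = 1e6)
  norm <- normalize_to_input(chip, ctrl, pseudocount = 1)
  expect_equal(norm$values$chr1, c(21 / 11, 1, 1))
  # self-normalization identity
  self <- normalize_to_input(chip, chip)
  expect_equal(self$values$chr1, rep(1, 3))
})

test_that("normalization is invariant to joint library rescaling", {
  withr::local_seed(5)
  v1 <- round(runif(40, 0, 30)); v2 <- round(runif(40, 0, 30))
  a <- normalize_to_input(make_track(v1, library_size = 1000),
                          make_track(v2, library_size = 2000))
  # multiply both libraries (counts and depths) by the same factor
  b <- normalize_to_input(make_track(v1 * 100, library_size = 1e5),
                          make_track(v2 * 100, library_size = 2e5))
  expect_equal(a$values$chr1, b$values$chr1, tolerance = 1e-12)
  expect_error(normalize_to_input(make_track(v1), make_track(v2[1:10])),
               "layout|width")
})

test_that("smooth_track preserves totals and flattens noise", {
  v <- c(rep(0, 50), 100, rep(0, 49))
  tr <- make_track(v, bin_width = 25)
  sm <- smooth_track(tr, window = 500)
  expect_equal(length(sm$values$chr1), length(v))
  expect_lt(max(sm$values$chr1), 100)
  expect_equal(mean(sm$values$chr1[30:70]), mean(v[30:70]),
               tolerance = 0.3)
  expect_equal(smooth_track(tr, 0)$values, tr$values)
})

test_that("tag_density counts overlapping reads and scales per million", {
  sz <- sizes1
  loci <- reference_loci("L1", "chr1", 5000)
  reads <- genomic_intervals(rep("chr1", 5),
                             c(4000, 4900, 6499, 1000, 8000),
                             c(4200, 5100, 6600, 1200, 8200), strand = "+")
  td <- tag_density(reads, loci, flank = 1500, sizes = sz,
                    library_size = 1e6)
  expect_equal(td$count, 3)   # edge-overlapping read [6499,6600) counts
  expect_equal(td$normalized, 3)
  td2 <- tag_density(reads, loci, 1500, sz, library_size = 2e5)
  expect_equal(td2$normalized, 15)
  expect_error(tag_density(reads, reference_loci("B", "chr1", 20000),
                           1500, sz), "bounds")
})

test_that("track-mode tag density sums the intersecting bins", {
  tr <- make_track(rep(1, 400), bin_width = 25, library_size = 1e6)
  loci <- reference_loci("L1", "chr1", 5000)
  td <- tag_density(tr, loci, flank = 1000, sizes = tr$sizes)
  expect_equal(td$count, 80)  # 2000 bp / 25 bp bins of value 1
  expect_equal(attr(td, "mode"), "track")
})

test_that("call_peaks recovers a planted enriched region", {
  withr::local_seed(99)
  sz <- toy_sizes(chr1 = 100000)
  bg <- random_reads(500, sz, max_len = 200)
  bg$start <- pmin(bg$start, 99800)
  bg$end <- bg$start + 200
  center <- 50000
  s <- round(rnorm(80, center, 100)) - 100
  planted <- genomic_intervals("chr1", s, s + 200, strand = "+")
  chip <- rbind(bg, planted); class(chip) <- class(bg)
  ctrl <- random_reads(500, sz, max_len = 200)
  peaks <- call_peaks(bin_density(chip, 25, sz), bin_density(ctrl, 25, sz))
  expect_equal(nrow(peaks), 1)
  expect_true(peaks$start < center && center < peaks$end)
  expect_true(abs(peaks$summit - center) < 500)
  expect_gte(peaks$fold_enrichment, 12)
})

test_that("call_peaks on an empty chip track returns no peaks", {
  sz <- toy_sizes(chr1 = 10000)
  empty <- bin_density(genomic_intervals(), 25, sz)
  ctrl <- bin_density(random_reads(100, sz), 25, sz)
  expect_equal(nrow(call_peaks(empty, ctrl)), 0)
  expect_error(call_peaks(empty, ctrl, alpha = 2), "alpha")
})

test_that("peak BED export round-trips fold enrichment and p-value", {
  pk <- structure(data.frame(chrom = "chr1", start = 100, end = 600,
                             summit = 350, fold_enrichment = 15.5,
                             p_value = 1e-8, name = "peak_1"),
                  class = c("peak_calls", "data.frame"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks(pk, f)
  back <- read_peaks(f)
  expect_equal(back$fold_enrichment, 15.5)
  expect_equal(back$p_value, 1e-8, tolerance = 1e-6)
})
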
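test_that("TSS matrix bins average the track and honour defaults", {
  # constant track -> every bin equals the constant
  tr <- make_track(rep(3, 800), bin_width = 25, sizes = toy_sizes(chr1 = 20000))
  loci <- reference_loci("L1", "chr1", 10000)
  pm <- collect_tss_matrix(tr, loci)
  expect_equal(ncol(pm$values), 100)           # 100 bins over +/-5 kb
  expect_equal(diff(pm$bin_offsets)[1], 100)   # 100 bp per bin
  expect_equal(unname(pm$values[1, ]), rep(3, 100))
})

test_that("a delta of signal lands in exactly one strand-correct bin", {
  sz <- toy_sizes(chr1 = 20000)
  v <- numeric(800); v[(12000 %/% 25) + 1] <- 5  # one 25bp bin at +2000
  tr <- make_track(v, bin_width = 25, sizes = sz)
  plus <- collect_tss_matrix(tr, reference_loci("P", "chr1", 10000, "+"))
  minus <- collect_tss_matrix(tr, reference_loci("M", "chr1", 10000, "-"))
  expect_equal(sum(plus$values > 0), 1)
  # +2000 of the anchor -> downstream half for + ; upstream half for -
  expect_gt(which(plus$values[1, ] > 0), 50)
  expect_lt(which(minus$values[1, ] > 0), 51)
  expect_equal(which(minus$values[1, ] > 0),
               101 - which(plus$values[1, ] > 0))
})

test_that("out-of-bounds windows are zero-filled and flagged", {
  tr <- make_track(rep(2, 80), bin_width = 25, sizes = toy_sizes(chr1 = 2000))
  pm <- collect_tss_matrix(tr, reference_loci("E", "chr1", 500), flank = 1000,
                           n_bins = 20)
  expect_true(pm$flagged[1])
  expect_equal(unname(pm$values[1, 1:5]), rep(0, 5))   # before chrom start
  expect_equal(unname(pm$values[1, 6:20]), rep(2, 15))
})

test_that("average_profile is the column mean and conserves the total", {
  pm <- structure(list(values = rbind(c(1, 2), c(3, 4)),
                       bin_offsets = c(-50, 50)), class = "profile_matrix")
  prof <- average_profile(pm)
  expect_equal(prof$mean, c(2, 3))
  expect_equal(mean(prof$mean), mean(pm$values))
  one <- structure(list(values = rbind(c(7, 9))), class = "profile_matrix")
  expect_equal(average_profile(one)$mean, c(7, 9))
  empty <- structure(list(values = matrix(numeric(0), 0, 2)),
                     class = "profile_matrix")
  expect_error(average_profile(empty), "empty")
})

test_that("gene-body matrix rescales bodies and keeps flat flanks flat", {
  sz <- toy_sizes(chr1 = 60000)
  g <- gene_models(c("g1", "g2"), "chr1", c("+", "-"),
                   c(10000, 30000), c(11000, 32500))
  # signal only inside gene bodies
  v <- numeric(2400)
  v[(10000 %/% 25 + 1):(11000 %/% 25)] <- 4
  v[(30000 %/% 25 + 1):(32500 %/% 25)] <- 4
  tr <- make_track(v, bin_width = 25, sizes = sz)
  gb <- collect_gene_body_matrix(tr, g)
  n_f <- 100  # 5000/50 flank bins
  expect_equal(ncol(gb$values), 2 * n_f + 100)
  body_cols <- (n_f + 1):(n_f + 100)
  expect_equal(unname(gb$values[, body_cols]),
               matrix(4, 2, 100))
  expect_equal(sum(gb$values[, -body_cols]), 0)
  expect_equal(as.character(unique(gb$segment[body_cols])), "body")
})

test_that("gene-body matrix drops genes shorter than the bin count", {
  sz <- toy_sizes(chr1 = 60000)
  g <- gene_models(c("ok", "tiny"), "chr1", "+", c(10000, 30000),
                   c(11000, 30050))
  tr <- make_track(numeric(2400), bin_width = 25, sizes = sz)
  expect_message(gb <- collect_gene_body_matrix(tr, g), "dropped")
  expect_equal(rownames(gb$values), "ok")
  expect_equal(gb$dropped, 1)
})

test_that("expression stratification splits deterministically with remainder on top", {
  g <- gene_models(sprintf("g%02d", 1:11), "chr1", "+",
                   seq(0, 10000, by = 1000), seq(500, 10500, by = 1000))
  expr <- stats::setNames(c(11:2, 2), g$gene_id)  # tie between g10 and g11
  groups <- stratify_by_expression(g, expr, 10)
  expect_equal(lengths(groups), stats::setNames(c(2, rep(1, 9)),
                                                names(groups)))
  expect_equal(groups$group_01, c("g01", "g02"))
  # tie at the bottom broken lexicographically
  expect_equal(groups$group_09, "g10")
  expect_equal(groups$group_10, "g11")
  # partition property: disjoint and exhaustive
  all_ids <- unlist(groups)
  expect_setequal(all_ids, g$gene_id)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_error(stratify_by_expression(g, expr[-1], 10), "g01")
})

test_that("sort_loci_by_score is stable and rejects missing scores", {
  loci <- reference_loci(c("a", "b", "c"), "chr1", c(10, 20, 30))
  sorted <- sort_loci_by_score(loci, c(5, 9, 1))
  expect_equal(sorted$locus_id, c("b", "a", "c"))
  same <- sort_loci_by_score(loci, c(2, 2, 2))
  expect_equal(same$locus_id, c("a", "b", "c"))
  expect_error(sort_loci_by_score(loci, c(a = 1, b = 2)), "missing")
})

test_that("acetylation tracks CpG content when the generator couples them", {
  spec <- synthetic_spec(seed = 14,
                         chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                         genes = c(active = 40, bivalent = 30,
                                   inactive = 40, primed = 10),
                         enhancers = c(active = 0, poised = 0),
                         marks = "H3K9ac")
  g <- build_genome(spec)
  loci <- tss_loci(g$genes)
  reads <- extend_reads(simulate_mark_reads(spec, g, "H3K9ac"), 200,
                        g$sizes)
  d <- tag_density(reads, loci, 1500, g$sizes)$normalized
  names(d) <- loci$locus_id
  cpg <- stats::setNames(g$truth$genes$cpg_count, g$truth$genes$gene_id)
  sorted <- sort_loci_by_score(loci, cpg)   # descending CpG content
  q <- split(sorted$locus_id, rep(1:4, each = 30))
  means <- vapply(q, function(ids) mean(d[ids]), numeric(1))
  # high-CpG promoters carry far more acetylation than low-CpG ones
  expect_gt(mean(means[1:2]), 3 * mean(means[3:4]))
  expect_gt(means[1], means[4])
  expect_gt(stats::cor(cpg[loci$locus_id], d, method = "spearman"), 0.5)
})

test_that("profile matrices export to TSV with offset headers", {
  tr <- make_track(rep(1, 400), bin_width = 25, sizes = toy_sizes(chr1 = 10000))
  pm <- collect_tss_matrix(tr, reference_loci("L1", "chr1", 5000),
                           flank = 1000, n_bins = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$locus_id, "L1")
  expect_equal(names(back)[2], "-900")
})
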
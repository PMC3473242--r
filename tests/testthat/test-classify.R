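fake_pm <- function(values, ids = sprintf("L%02d", seq_len(nrow(values))),
                    offsets = NULL) {
  structure(list(loci = reference_loci(ids, "chr1",
                                       seq_len(nrow(values)) * 1000),
                 values = matrix(values, nrow = nrow(values),
                                 dimnames = list(ids, NULL)),
                 bin_offsets = offsets %||%
                   seq(-length(values[1, ]) / 2 * 100 + 50, by = 100,
                       length.out = ncol(values)),
                 mode = "input_normalized",
                 flagged = rep(FALSE, nrow(values))),
            class = "profile_matrix")
}

test_that("k-means separates two well-separated 1-D groups", {
  v <- matrix(c(0, 0.1, 0.2, 10, 10.1), ncol = 1)
  mmm <- multi_mark_matrix(list(m = fake_pm(v)))
  fit <- kmeans_cluster(mmm, k = 2, seed = 3)
  # the optimal 2-partition (exhaustive WCSS check) splits {1,2,3}|{4,5}
  expect_equal(length(unique(fit$labels[1:3])), 1)
  expect_equal(length(unique(fit$labels[4:5])), 1)
  expect_true(fit$labels[1] != fit$labels[4])
  # renumbering: cluster 1 has the higher first-mark signal
  expect_equal(unname(fit$labels[4]), 1)
})

test_that("k-means is deterministic given the seed", {
  withr::local_seed(17)
  v <- matrix(runif(60), ncol = 2)
  mmm <- multi_mark_matrix(list(a = fake_pm(v[, 1, drop = FALSE]),
                                b = fake_pm(v[, 2, drop = FALSE])))
  f1 <- kmeans_cluster(mmm, 3, seed = 5)
  f2 <- kmeans_cluster(mmm, 3, seed = 5)
  expect_identical(f1$labels, f2$labels)
})

test_that("duplicate-row degenerate input terminates with empty clusters", {
  v <- matrix(rep(1, 6), ncol = 1)
  mmm <- multi_mark_matrix(list(m = fake_pm(v)))
  expect_warning(fit <- kmeans_cluster(mmm, 2, seed = 1), "distinct")
  expect_equal(length(unique(fit$labels)), 1)
  expect_error(kmeans_cluster(mmm, 10, seed = 1), "exceeds")
})

test_that("restarts never worsen the within-cluster sum of squares", {
  withr::local_seed(23)
  v <- matrix(runif(90), ncol = 3)
  mmm <- multi_mark_matrix(list(m = fake_pm(v)))
  w1 <- kmeans_cluster(mmm, 4, seed = 2, n_restarts = 1)$wcss
  w10 <- kmeans_cluster(mmm, 4, seed = 2, n_restarts = 10)$wcss
  expect_lte(w10, w1 + 1e-9)
})

fake_clusters <- function(labels, ids = names(labels)) {
  structure(list(labels = stats::setNames(labels, ids), k =
                   length(unique(labels))), class = "kmeans_clusters")
}

test_that("promoter rules assign active, bivalent and inactive correctly", {
  # three clusters of two loci each with the canonical mark signatures
  ids <- sprintf("L%d", 1:6)
  labels <- fake_clusters(rep(1:3, each = 2), ids)
  summaries <- rbind(
    c(8, 10, 0.5), c(8, 10, 0.5),    # PolII 8x, K4me3 10x, K27me3 0.5x
    c(1.2, 5, 4), c(1.2, 5, 4),      # bivalent signature
    c(0.8, 0.9, 1), c(0.8, 0.9, 1))  # nothing marked
  colnames(summaries) <- c("PolII", "H3K4me3", "H3K27me3")
  rownames(summaries) <- ids
  bg <- c(PolII = 1, H3K4me3 = 1, H3K27me3 = 1)
  cls <- classify_promoters(labels, summaries, bg)
  expect_equal(cls$label, rep(c("active", "bivalent", "inactive"),
                              each = 2))
  # every locus labelled exactly once
  expect_equal(nrow(cls), 6)
  # bivalent rule precedes active: K4me3 + K27me3 + PolII -> bivalent
  summaries[3:4, "PolII"] <- 9
  cls2 <- classify_promoters(labels, summaries, bg)
  expect_equal(unique(cls2$label[3:4]), "bivalent")
})

test_that("promoter labels are insensitive to the presence factor when marks are well separated", {
  ids <- sprintf("L%d", 1:6)
  labels <- fake_clusters(rep(1:3, each = 2), ids)
  summaries <- rbind(c(8, 10, 0.5), c(8, 10, 0.5), c(1.2, 5, 4),
                     c(1.2, 5, 4), c(0.8, 0.9, 1), c(0.8, 0.9, 1))
  colnames(summaries) <- c("PolII", "H3K4me3", "H3K27me3")
  rownames(summaries) <- ids
  bg <- c(PolII = 1, H3K4me3 = 1, H3K27me3 = 1)
  for (f in c(1.5, 2, 3)) {
    cls <- classify_promoters(labels, summaries, bg, presence_factor = f)
    expect_equal(cls$label, rep(c("active", "bivalent", "inactive"),
                                each = 2), info = paste("factor", f))
  }
})

test_that("enhancers split by central H3K27ac against background", {
  v <- rbind(c(0.4, 5, 5, 0.4),    # central 5x background
             c(0.4, 0.8, 0.8, 0.4),
             c(0, 0, 0, 0))
  pm <- fake_pm(v, offsets = c(-750, -250, 250, 750))
  loci <- pm$loci
  cls <- classify_enhancers(loci, pm, background = 1)
  expect_equal(cls$label, c("active", "poised", "poised"))
  expect_equal(attr(cls, "central_flank"), 500)
  all0 <- classify_enhancers(loci, fake_pm(matrix(0, 3, 4),
                                           offsets = c(-750, -250, 250, 750)),
                             background = 1)
  expect_true(all(all0$label == "poised"))
})

test_that("mark correlation handles perfect, inverse and degenerate cases", {
  d <- cbind(K9 = c(1, 2, 3, 4), K14 = c(2, 4, 6, 8), inv = c(4, 3, 2, 1))
  r <- mark_correlation(d, log_transform = FALSE)
  expect_equal(r["K9", "K14"], 1)
  expect_equal(r["K9", "inv"], -1)
  expect_equal(diag(r), c(K9 = 1, K14 = 1, inv = 1))
  expect_true(isSymmetric(r))
  # zero variance -> missing, not zero
  d0 <- cbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  r0 <- mark_correlation(d0)
  expect_true(is.na(r0["a", "flat"]))
  expect_error(mark_correlation(d[1:2, ]), "3 loci")
})

test_that("correlation matrices are positive semi-definite", {
  withr::local_seed(4)
  d <- matrix(rlnorm(500 * 4), ncol = 4,
              dimnames = list(NULL, letters[1:4]))
  r <- mark_correlation(d)
  expect_gte(min(eigen(r, symmetric = TRUE)$values), -1e-8)
})

test_that("ratio statistic applies the pseudocount and ranks groups", {
  k14 <- c(a1 = 4, a2 = 1, i1 = 4, i2 = 6)
  k9 <- c(a1 = 4, a2 = 1, i1 = 1, i2 = 1)
  res <- ratio_statistic(k14, k9, c("a1", "a2"), c("i1", "i2"))
  expect_equal(unname(res$ratio["i1"]), 2.5)  # (4+1)/(1+1)
  expect_equal(unname(res$medians["active"]), 1)
  expect_gt(res$medians["inactive"], res$medians["active"])
  expect_equal(res$direction, "inactive > active")
  expect_error(ratio_statistic(k14, k9, character(0), c("i1")), "non-empty")
  expect_error(ratio_statistic(k14, k9, c("a1", "i1"), c("i1")), "overlap")
})

test_that("equal densities give unit ratios and a non-significant test", {
  k <- stats::setNames(rep(3, 20), sprintf("g%d", 1:20))
  res <- ratio_statistic(k, k, sprintf("g%d", 1:10), sprintf("g%d", 11:20))
  expect_true(all(res$ratio == 1))
  expect_gt(res$p_value, 0.4)
})

test_that("primed selection orders by ratio with K14 then id tie-breaks", {
  ratio <- stats::setNames(c(3, 2, 1, 0.5, 0.2, 2), sprintf("i%d", 1:6))
  res <- structure(list(ratio = ratio), class = "ratio_result")
  k14 <- stats::setNames(c(5, 1, 1, 1, 1, 9), names(ratio))
  top2 <- select_primed_inactive(names(ratio), res, k14, 2)
  expect_equal(top2, c("i1", "i6"))  # tie at ratio 2: i6 has higher K14
  top3 <- select_primed_inactive(names(ratio), res, k14, 3)
  expect_equal(top3, c("i1", "i6", "i2"))
  expect_error(select_primed_inactive(names(ratio), res, k14, 10),
               "exceeds")
})
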
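# Chromatin-state inference: k-means clustering, promoter/enhancer class
# assignment, cross-mark correlation and the K14/K9 ratio statistic.

#' Multi-mark feature matrix
#'
#' Binds per-mark profile matrices (identical loci, identical bin counts)
#' into one loci x (marks * bins) feature matrix for clustering.
#'
#' @param matrices named list of `profile_matrix` objects, one per mark;
#'   names give the mark order.
#' @return object of class `multi_mark_matrix`: `loci`, `marks`,
#'   `matrices`, and the concatenated `features` matrix.
#' @export
multi_mark_matrix <- function(matrices) {
  abort_if(is.null(names(matrices)) || any(names(matrices) == ""),
           "matrices must be a named list (one name per mark)")
  marks <- names(matrices)
  ref <- matrices[[1]]$loci$locus_id
  for (m in marks) {
    abort_if(!identical(matrices[[m]]$loci$locus_id, ref),
             "mark ", m, ": loci differ from first mark")
    abort_if(ncol(matrices[[m]]$values) != ncol(matrices[[1]]$values),
             "mark ", m, ": bin count differs from first mark")
  }
  features <- do.call(cbind, lapply(matrices, function(x) x$values))
  structure(list(loci = matrices[[1]]$loci, marks = marks,
                 matrices = matrices, features = features),
            class = "multi_mark_matrix")
}

# per-mark log(x+1) then per-mark standardization (constant marks left 0)
scale_features <- function(mmm) {
  blocks <- lapply(mmm$marks, function(m) {
    v <- log1p(mmm$matrices[[m]]$values)
    s <- stats::sd(v)
    if (is.na(s) || s == 0) return(v * 0)
    (v - mean(v)) / s
  })
  do.call(cbind, blocks)
}

#' K-means clustering of a multi-mark matrix
#'
#' Lloyd's algorithm on per-mark `log(x + 1)`-scaled, per-mark
#' standardized features (so high-dynamic-range marks do not dominate the
#' distance).  The best of `n_restarts` random starts by within-cluster
#' sum of squares is kept; the run is deterministic given `seed`.
#' Cluster ids are renumbered by descending mean signal of the first mark
#' so reports are stable across seeds.  When the matrix has fewer
#' distinct rows than `k` (degenerate input) the distinct rows seed the
#' clusters and the surplus clusters stay empty.
#'
#' @param matrix `multi_mark_matrix`.
#' @param k number of clusters (>= 2, <= number of loci).
#' @param seed integer seed.
#' @param n_restarts random restarts (default 10).
#' @return list of class `kmeans_clusters`: `labels` (named by locus id),
#'   `centers`, `wcss`, `k`, `marks`.
#' @export
kmeans_cluster <- function(matrix, k, seed, n_restarts = 10) {
  abort_if(k < 2, "k must be at least 2")
  abort_if(k > nrow(matrix$loci), "k exceeds the number of loci")
  x <- scale_features(matrix)
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    key <- apply(x, 1, paste, collapse = "\r")
    labels <- match(key, unique(key))
    centers <- x[!duplicated(key), , drop = FALSE]
    warning("only ", n_distinct, " distinct rows for k = ", k,
            "; surplus clusters left empty", call. = FALSE)
    fit <- list(cluster = labels, centers = centers, tot.withinss = 0)
  } else {
    fit <- with_seed(seed, {
      stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100,
                    algorithm = "Lloyd")
    })
  }
  # stable renumbering by descending first-mark mean signal
  nb <- ncol(matrix$matrices[[1]]$values)
  first_block <- log1p(matrix$matrices[[1]]$values)
  cl_mean <- vapply(sort(unique(fit$cluster)), function(c_) {
    mean(first_block[fit$cluster == c_, , drop = FALSE])
  }, numeric(1))
  remap <- match(seq_along(cl_mean), order(-cl_mean))
  labels <- remap[fit$cluster]
  names(labels) <- matrix$loci$locus_id
  structure(list(labels = labels,
                 centers = fit$centers[order(-cl_mean), , drop = FALSE],
                 wcss = fit$tot.withinss, k = k, marks = matrix$marks),
            class = "kmeans_clusters")
}

#' Per-locus mark density summaries
#'
#' One number per locus and mark: the mean of the profile bins within
#' `central_flank` bases of the anchor, the statistic cluster summaries
#' and presence calls are based on.
#'
#' @param matrix `multi_mark_matrix` built from input-normalized profiles.
#' @param central_flank half-width of the central window in bases
#'   (default 1000).
#' @return loci x marks numeric matrix.
#' @export
mark_summaries <- function(matrix, central_flank = 1000) {
  out <- vapply(matrix$marks, function(m) {
    pm <- matrix$matrices[[m]]
    off <- pm$bin_offsets %||% seq_len(ncol(pm$values))
    central <- abs(off) <= central_flank
    if (!any(central)) central <- rep(TRUE, length(off))
    rowMeans(pm$values[, central, drop = FALSE])
  }, numeric(nrow(matrix$loci)))
  rownames(out) <- matrix$loci$locus_id
  out
}

#' Classify promoters into active / bivalent / inactive
#'
#' A cluster is "marked" for a modification when its mean central density
#' is at least `presence_factor` times the genome-wide background for
#' that mark.  Clusters marked for both H3K4me3 and H3K27me3 are
#' bivalent; clusters marked for H3K4me3 and Pol II but not H3K27me3 are
#' active; everything else is inactive.  Labels propagate to loci via
#' cluster membership.
#'
#' @param clusters `kmeans_clusters`.
#' @param summaries loci x marks matrix from [mark_summaries()], computed
#'   on input-normalized densities; must contain columns named
#'   `H3K4me3`, `H3K27me3` and `PolII`.
#' @param background named per-mark genome-wide background level (e.g.
#'   [track_median()] of each normalized track).
#' @param presence_factor presence threshold multiplier (default 2).
#' @return object of class `promoter_classification`: data.frame
#'   `locus_id`, `cluster`, `label`; per-cluster mark means as attribute
#'   `cluster_summary`, the presence calls as attribute `marked`.
#' @export
classify_promoters <- function(clusters, summaries, background,
                               presence_factor = 2) {
  need <- c("H3K4me3", "H3K27me3", "PolII")
  abort_if(!all(need %in% colnames(summaries)),
           "summaries must contain marks: ", paste(need, collapse = ", "))
  abort_if(!all(colnames(summaries) %in% names(background)),
           "background missing for some marks")
  ks <- sort(unique(clusters$labels))
  cl_sum <- t(vapply(ks, function(c_) {
    colMeans(summaries[clusters$labels == c_, , drop = FALSE])
  }, numeric(ncol(summaries))))
  rownames(cl_sum) <- ks
  marked <- sweep(cl_sum, 2, presence_factor *
                    background[colnames(cl_sum)], ">=")
  label <- ifelse(marked[, "H3K4me3"] & marked[, "H3K27me3"], "bivalent",
           ifelse(marked[, "H3K4me3"] & marked[, "PolII"], "active",
                  "inactive"))
  res <- data.frame(locus_id = names(clusters$labels),
                    cluster = unname(clusters$labels),
                    label = label[match(clusters$labels, ks)],
                    stringsAsFactors = FALSE)
  attr(res, "cluster_summary") <- cl_sum
  attr(res, "marked") <- marked
  attr(res, "presence_factor") <- presence_factor
  class(res) <- c("promoter_classification", "data.frame")
  res
}

#' Classify enhancers into active / poised by H3K27ac
#'
#' The per-locus statistic is the mean of the H3K27ac profile bins within
#' `central_flank` bases of the enhancer anchor; loci at or above
#' `presence_factor` times the genome-wide background are active, the
#' rest poised.
#'
#' @param loci enhancer [reference_loci()].
#' @param k27ac `profile_matrix` of H3K27ac over the same loci
#'   (input-normalized).
#' @param background genome-wide H3K27ac background (e.g.
#'   [track_median()] of the normalized track).
#' @param presence_factor presence threshold multiplier (default 2).
#' @param central_flank half-width of the central window (default 500).
#' @return object of class `enhancer_classification`: data.frame
#'   `locus_id`, `statistic`, `label`; thresholds kept as attributes.
#' @export
classify_enhancers <- function(loci, k27ac, background,
                               presence_factor = 2, central_flank = 500) {
  abort_if(!identical(k27ac$loci$locus_id, loci$locus_id),
           "matrix rows do not correspond to the enhancer loci")
  off <- k27ac$bin_offsets %||% seq_len(ncol(k27ac$values))
  central <- abs(off) <= central_flank
  if (!any(central)) central <- rep(TRUE, length(off))
  stat <- rowMeans(k27ac$values[, central, drop = FALSE])
  res <- data.frame(locus_id = loci$locus_id, statistic = stat,
                    label = ifelse(stat >= presence_factor * background,
                                   "active", "poised"),
                    stringsAsFactors = FALSE)
  attr(res, "presence_factor") <- presence_factor
  attr(res, "central_flank") <- central_flank
  attr(res, "background") <- background
  class(res) <- c("enhancer_classification", "data.frame")
  res
}

#' Cross-mark correlation matrix
#'
#' Pearson correlation between per-locus mark densities over a shared
#' locus list, computed by default on `log(x + 1)`-transformed densities
#' (pairwise complete).  A zero-variance mark yields `NA` against every
#' other mark, reported as missing rather than 0.
#'
#' @param densities loci x marks numeric matrix (e.g. normalized tag
#'   densities over TSS windows).
#' @param method only `"pearson"` is supported.
#' @param log_transform transform densities with `log1p` first (default
#'   TRUE).
#' @return symmetric marks x marks correlation matrix with unit diagonal.
#' @export
mark_correlation <- function(densities, method = "pearson",
                             log_transform = TRUE) {
  method <- match.arg(method, "pearson")
  abort_if(nrow(densities) < 3, "need at least 3 loci")
  x <- if (log_transform) log1p(densities) else densities
  suppressWarnings(
    r <- stats::cor(x, method = method, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' H3K14ac/H3K9ac ratio statistic
#'
#' Per-locus ratio `(k14 + p) / (k9 + p)` on per-million-normalized tag
#' densities, with group medians for a disjoint active and inactive gene
#' set and a one-sided rank-sum (Wilcoxon) test of the hypothesis that
#' inactive-gene ratios exceed active-gene ratios.
#'
#' @param k14,k9 named numeric vectors of normalized tag densities
#'   (names = locus ids, identical sets).
#' @param active_set,inactive_set disjoint character vectors of locus ids.
#' @param pseudocount additive pseudocount (default 1).
#' @return object of class `ratio_result`: list with `ratio` (named
#'   vector), `groups`, `medians`, `statistic`, `p_value`, `direction`.
#' @export
ratio_statistic <- function(k14, k9, active_set, inactive_set,
                            pseudocount = 1.0) {
  abort_if(length(active_set) == 0 || length(inactive_set) == 0,
           "both groups must be non-empty")
  abort_if(length(intersect(active_set, inactive_set)) > 0,
           "active and inactive sets overlap")
  abort_if(!all(c(active_set, inactive_set) %in% names(k14)) ||
             !all(names(k14) %in% names(k9)),
           "densities missing for some loci")
  ratio <- (k14 + pseudocount) / (k9[names(k14)] + pseudocount)
  med <- c(active = stats::median(ratio[active_set]),
           inactive = stats::median(ratio[inactive_set]))
  wt <- suppressWarnings(
    stats::wilcox.test(ratio[inactive_set], ratio[active_set],
                       alternative = "greater", exact = FALSE))
  structure(list(ratio = ratio,
                 groups = list(active = active_set,
                               inactive = inactive_set),
                 medians = med,
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 direction = if (med["inactive"] > med["active"])
                   "inactive > active" else "inactive <= active",
                 pseudocount = pseudocount),
            class = "ratio_result")
}

#' Select primed inactive promoters
#'
#' The top `n` inactive loci by K14/K9 ratio: inactive genes whose
#' H3K14ac clearly exceeds their H3K9ac, the candidates poised for
#' stimulus-dependent activation.  Ties are broken by higher absolute K14
#' density, then by locus id; the result is in descending-ratio order.
#'
#' @param inactive_loci character vector of inactive locus ids.
#' @param ratios `ratio_result` (its `ratio` vector must cover the loci).
#' @param k14 named K14 densities used for tie breaking.
#' @param n number of loci to select (default 500).
#' @return character vector of `n` locus ids, highest ratio first.
#' @export
select_primed_inactive <- function(inactive_loci, ratios, k14, n = 500) {
  abort_if(n > length(inactive_loci),
           "n = ", n, " exceeds available inactive loci (",
           length(inactive_loci), ")")
  r <- ratios$ratio[inactive_loci]
  abort_if(any(is.na(r)), "ratio missing for some inactive loci")
  ord <- order(-r, -k14[inactive_loci], inactive_loci)
  inactive_loci[ord][seq_len(n)]
}
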
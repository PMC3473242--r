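# Strand-oriented locus x bin signal matrices and composite profiles.

# Per-base Rle view of a binned track for one chromosome.
track_rle <- function(track, chrom) {
  v <- track$values[[chrom]]
  abort_if(is.null(v), "track lacks chromosome ", chrom)
  len <- track$sizes[[chrom]] %||% (length(v) * track$bin_width)
  widths <- rep(track$bin_width, length(v))
  widths[length(widths)] <- len - (length(v) - 1) * track$bin_width
  S4Vectors::Rle(v, widths)
}

# Mean track value over windows [start, end) (0-based half-open), with
# bases outside [0, len) contributing zero signal (zero padding).  Rows of
# `start`/`end` index windows; nominal widths are used as denominators.
window_means_padded <- function(rle, start, end) {
  len <- length(rle)
  width <- end - start
  cs <- pmax(pmin(start + 1, len + 1), 1)  # 1-based clipped
  ce <- pmax(pmin(end, len), 0)
  sums <- numeric(length(start))
  ok <- cs <= ce & width > 0
  if (any(ok)) {
    v <- IRanges::Views(rle, start = cs[ok], end = ce[ok])
    sums[ok] <- IRanges::viewSums(v)
  }
  ifelse(width > 0, sums / width, 0)
}

#' TSS-anchored profile matrix
#'
#' For each reference locus, the window `[anchor - flank, anchor + flank)`
#' is divided into `n_bins` equal bins (100 bp bins at the defaults) and
#' each bin holds the base-weighted mean of the track values it covers.
#' Rows of minus-strand loci are reversed so that bin 1 is always the
#' 5'-most; windows running past a chromosome end are zero-filled on the
#' missing side and the locus is flagged.
#'
#' @param track a [density_track()] (raw or input-normalized).
#' @param loci [reference_loci()].
#' @param flank half-window in bases (default 5000).
#' @param n_bins number of equal bins across the window (default 100).
#' @return object of class `profile_matrix`: list with `loci`, `values`
#'   (loci x bins matrix, rownames = locus ids), `bin_offsets` (bin
#'   midpoints relative to the anchor, 5' to 3'), `mode`, and `flagged`.
#' @export
collect_tss_matrix <- function(track, loci, flank = 5000, n_bins = 100) {
  abort_if(n_bins <= 0, "n_bins must be positive")
  abort_if(flank <= 0, "flank must be positive")
  bounds <- round(seq(-flank, flank, length.out = n_bins + 1))
  values <- matrix(0, nrow = nrow(loci), ncol = n_bins,
                   dimnames = list(loci$locus_id, NULL))
  flagged <- logical(nrow(loci))
  for (chrom in unique(loci$chrom)) {
    sel <- which(loci$chrom == chrom)
    rle <- track_rle(track, chrom)
    len <- length(rle)
    anchors <- loci$anchor[sel]
    starts <- rep(anchors, each = n_bins) + bounds[-length(bounds)]
    ends <- rep(anchors, each = n_bins) + bounds[-1]
    m <- matrix(window_means_padded(rle, starts, ends),
                nrow = length(sel), ncol = n_bins, byrow = TRUE)
    values[sel, ] <- m
    flagged[sel] <- anchors - flank < 0 | anchors + flank > len
  }
  minus <- loci$strand == "-"
  if (any(minus)) values[minus, ] <- values[minus, n_bins:1, drop = FALSE]
  mids <- (bounds[-length(bounds)] + bounds[-1]) / 2
  structure(list(loci = loci, values = values, bin_offsets = mids,
                 mode = track$mode, flagged = flagged),
            class = "profile_matrix")
}

#' Composite (average) profile of a matrix
#'
#' @param matrix a `profile_matrix` (or `gene_body_profile`).
#' @return data.frame with `offset` (bin midpoint or segment label
#'   position), column-wise `mean` and standard error `se`.
#' @export
average_profile <- function(matrix) {
  v <- matrix$values
  abort_if(is.null(v) || nrow(v) == 0, "empty profile matrix")
  m <- colMeans(v)
  se <- apply(v, 2, stats::sd) / sqrt(nrow(v))
  data.frame(offset = matrix$bin_offsets %||% seq_along(m),
             mean = m, se = se)
}

#' Gene-body scaled profile matrix
#'
#' Each gene contributes a fixed-length row: `flank / flank_bin_width`
#' fixed-width bins upstream of the TSS, `body_bins` bins whose width
#' scales with the gene length (so every gene body maps onto the same 100
#' columns), and the downstream flank.  Bin values are base-weighted means
#' of the track.  Minus-strand genes are fully reversed so rows always run
#' 5' to 3'.  Genes shorter than `body_bins` bases cannot be rescaled and
#' are dropped with a message.
#'
#' @param track a [density_track()].
#' @param genes [gene_models()].
#' @param flank flank span in bases (default 5000).
#' @param body_bins number of gene-body bins (default 100).
#' @param flank_bin_width width of flank bins in bases (default 50).
#' @return object of class `gene_body_profile`: `values` matrix, `segment`
#'   factor labelling columns upstream/body/downstream, `loci`, `dropped`.
#' @export
collect_gene_body_matrix <- function(track, genes, flank = 5000,
                                     body_bins = 100, flank_bin_width = 50) {
  abort_if(nrow(genes) == 0, "empty gene list")
  abort_if(flank %% flank_bin_width != 0,
           "flank must be a multiple of flank_bin_width")
  keep <- (genes$end - genes$start) >= body_bins
  if (any(!keep)) {
    message(sum(!keep), " gene(s) shorter than ", body_bins,
            " bases dropped from gene-body profile")
  }
  genes <- genes[keep, , drop = FALSE]
  abort_if(nrow(genes) == 0, "no gene long enough for gene-body profile")
  n_f <- flank %/% flank_bin_width
  n_cols <- 2 * n_f + body_bins
  values <- matrix(0, nrow = nrow(genes), ncol = n_cols,
                   dimnames = list(genes$gene_id, NULL))
  for (chrom in unique(genes$chrom)) {
    sel <- which(genes$chrom == chrom)
    rle <- track_rle(track, chrom)
    for (i in sel) {
      L <- genes$end[i] - genes$start[i]
      body_bounds <- genes$start[i] + round((0:body_bins) * L / body_bins)
      up_bounds <- seq(genes$start[i] - flank, genes$start[i],
                       by = flank_bin_width)
      dn_bounds <- seq(genes$end[i], genes$end[i] + flank,
                       by = flank_bin_width)
      bounds <- c(up_bounds, body_bounds[-1], dn_bounds[-1])
      row <- window_means_padded(rle, bounds[-length(bounds)], bounds[-1])
      if (genes$strand[i] == "-") row <- rev(row)
      values[i, ] <- row
    }
  }
  segment <- factor(rep(c("upstream", "body", "downstream"),
                        c(n_f, body_bins, n_f)),
                    levels = c("upstream", "body", "downstream"))
  structure(list(loci = tss_loci(genes), values = values,
                 segment = segment, dropped = sum(!keep),
                 mode = track$mode),
            class = c("gene_body_profile", "profile_matrix"))
}

#' Stratify genes by expression level
#'
#' Genes are ranked in descending expression order and split into
#' `n_groups` contiguous groups of near-equal size; when the division is
#' not exact the remainder goes to the top groups.  Group 1 holds the most
#' expressed genes.  Ties at a group boundary are broken by gene id
#' (lexicographic) so membership is deterministic.
#'
#' @param genes [gene_models()].
#' @param expr named numeric vector, gene id -> expression level; every
#'   gene must have a value.
#' @param n_groups number of groups (default 10 deciles).
#' @return named list `group_01` ... of gene id character vectors.
#' @export
stratify_by_expression <- function(genes, expr, n_groups = 10) {
  abort_if(n_groups < 2, "n_groups must be at least 2")
  missing <- setdiff(genes$gene_id, names(expr))
  abort_if(length(missing) > 0,
           "missing expression for gene(s): ",
           paste(utils::head(missing, 10), collapse = ", "))
  e <- expr[genes$gene_id]
  ord <- order(-e, genes$gene_id)
  ids <- genes$gene_id[ord]
  n <- length(ids)
  base <- n %/% n_groups
  sizes <- rep(base, n_groups)
  rem <- n - base * n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  groups <- split(ids, rep(seq_len(n_groups), sizes))
  names(groups) <- sprintf("group_%02d", seq_len(n_groups))
  groups
}

#' Sort reference loci by a per-locus score
#'
#' Stable sort: ties keep input order (used e.g. to order CpG islands by
#' their CpG content for heatmap display).
#'
#' @param loci [reference_loci()].
#' @param scores numeric vector aligned with `loci`, or named by locus id.
#' @param descending sort direction (default TRUE, highest first).
#' @return reordered [reference_loci()].
#' @export
sort_loci_by_score <- function(loci, scores, descending = TRUE) {
  if (!is.null(names(scores))) {
    abort_if(!all(loci$locus_id %in% names(scores)),
             "missing score for some loci")
    scores <- scores[loci$locus_id]
  }
  abort_if(length(scores) != nrow(loci) || any(is.na(scores)),
           "need one non-missing score per locus")
  ord <- order(if (descending) -scores else scores)
  out <- loci[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(loci)
  out
}

#' Export a profile matrix as TSV
#'
#' One row per locus; the header carries the bin midpoint offsets.
#'
#' @param matrix `profile_matrix`.
#' @param path output path.
#' @export
write_profile_matrix <- function(matrix, path) {
  df <- data.frame(locus_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- as.character(matrix$bin_offsets %||%
                                  seq_len(ncol(matrix$values)))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Export a composite profile as two-column TSV (offset, mean)
#' @param profile output of [average_profile()].
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  data.table::fwrite(profile, path, sep = "\t", quote = FALSE)
  invisible(path)
}
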
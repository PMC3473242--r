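#' Binned density track
#'
#' Per-chromosome fixed-width bin arrays.  For raw tracks each bin holds
#' the maximal number of reads simultaneously overlapping any single base
#' of the bin (max-overlap semantics); input-normalized tracks hold
#' enrichment ratios.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param bin_width bin width in bases.
#' @param library_size total read count the track was built from.
#' @param sizes optional [chrom_sizes()] recorded for bounds checks.
#' @param mode `"raw"` or `"input_normalized"`.
#' @param name optional track label used in WIG headers.
#' @return object of class `density_track`.
#' @export
density_track <- function(values, bin_width, library_size = NA_real_,
                          sizes = NULL, mode = "raw", name = NULL) {
  abort_if(bin_width <= 0, "bin_width must be positive")
  abort_if(any(vapply(values, function(v) any(v < 0), logical(1))),
           "density_track: negative bin values")
  if (!is.null(sizes)) {
    abort_if(!setequal(names(values), names(sizes)),
             "density_track: chromosomes do not match chrom_sizes")
    for (chrom in names(sizes)) {
      abort_if(length(values[[chrom]]) != ceiling(sizes[[chrom]] / bin_width),
               "density_track: wrong bin count for ", chrom)
    }
    values <- values[names(sizes)]
  }
  structure(list(values = values, bin_width = as.integer(bin_width),
                 library_size = library_size, sizes = sizes,
                 mode = mode, name = name),
            class = "density_track")
}

#' @export
print.density_track <- function(x, ...) {
  nb <- sum(vapply(x$values, length, numeric(1)))
  cat(sprintf("density_track (%s): %d chromosome(s), %d bins of %d bp, library %s\n",
              x$mode, length(x$values), nb, x$bin_width,
              format(x$library_size)))
  invisible(x)
}

#' Extend reads to fragment length
#'
#' Sequenced reads mark only the 5' end of each immunoprecipitated
#' fragment; each read is therefore extended to the expected fragment
#' length in its own direction before any density computation: a `+`
#' strand read `[s, e)` becomes `[s, s + length)` and a `-` strand read
#' becomes `[e - length, e)`, clamped to the chromosome.
#'
#' @param reads [genomic_intervals()]; strand `"."` is treated as `"+"`
#'   with a warning.
#' @param length fragment length in bases (default 200).
#' @param sizes [chrom_sizes()] used for clamping.
#' @return extended [genomic_intervals()]; read count is preserved.
#' @export
extend_reads <- function(reads, length = 200, sizes) {
  abort_if(length <= 0, "extension length must be positive")
  check_bounds(reads, sizes)
  strand <- effective_strand(reads$strand)
  plus <- strand == "+"
  start <- ifelse(plus, reads$start, reads$end - length)
  end <- ifelse(plus, reads$start + length, reads$end)
  lim <- unname(sizes[reads$chrom])
  out <- reads
  out$start <- pmax(start, 0)
  out$end <- pmin(end, lim)
  out$strand <- strand
  validate_intervals(out, "extend_reads")
  out
}

#' Bin a read set into a max-overlap density track
#'
#' The genome is tiled with fixed-width bins (default 25 bp) and each bin
#' records the maximal per-base count of overlapping (already extended)
#' reads within the bin.
#'
#' @param extended extended reads as [genomic_intervals()]; reads beyond a
#'   chromosome end are an error (clamping belongs to [extend_reads()]).
#' @param bin_width bin width in bases (default 25).
#' @param sizes [chrom_sizes()].
#' @return a raw [density_track()] with `library_size = nrow(extended)`.
#' @export
bin_density <- function(extended, bin_width = 25, sizes) {
  abort_if(bin_width <= 0, "bin_width must be positive")
  check_bounds(extended, sizes)
  values <- lapply(names(sizes), function(chrom) {
    len <- sizes[[chrom]]
    n_bins <- ceiling(len / bin_width)
    sel <- extended$chrom == chrom
    if (!any(sel)) return(numeric(n_bins))
    cov <- IRanges::coverage(as_iranges0(extended$start[sel],
                                         extended$end[sel]),
                             width = len)
    starts <- seq(1, by = bin_width, length.out = n_bins)
    v <- IRanges::Views(cov, start = starts,
                        end = pmin(starts + bin_width - 1, len))
    as.numeric(IRanges::viewMaxs(v))
  })
  names(values) <- names(sizes)
  density_track(values, bin_width = bin_width,
                library_size = nrow(extended), sizes = sizes)
}

check_compatible <- function(a, b) {
  abort_if(a$bin_width != b$bin_width, "tracks differ in bin width")
  abort_if(!identical(names(a$values), names(b$values)) ||
             !identical(lengths(a$values), lengths(b$values)),
           "tracks differ in chromosome layout")
}

#' Normalize a ChIP track to its input control
#'
#' Both tracks are scaled to reads-per-million of their libraries; each
#' bin then holds `(chip_pm + p) / (control_pm + p)` with pseudocount `p`
#' on the per-million scale.  Identical tracks normalize to 1 everywhere,
#' and the result is invariant to jointly rescaling both library depths.
#'
#' @param chip,control raw [density_track()]s with identical layout and
#'   positive library sizes.
#' @param pseudocount additive pseudocount in per-million units (default 1).
#' @return an input-normalized [density_track()].
#' @export
normalize_to_input <- function(chip, control, pseudocount = 1.0) {
  check_compatible(chip, control)
  abort_if(is.na(chip$library_size) || chip$library_size <= 0 ||
             is.na(control$library_size) || control$library_size <= 0,
           "both library sizes must be positive")
  fc <- 1e6 / chip$library_size
  fi <- 1e6 / control$library_size
  values <- Map(function(c_, i_) (c_ * fc + pseudocount) /
                  (i_ * fi + pseudocount),
                chip$values, control$values)
  density_track(values, bin_width = chip$bin_width,
                library_size = chip$library_size, sizes = chip$sizes,
                mode = "input_normalized", name = chip$name)
}

#' Smooth a track with a centered rolling mean
#'
#' Replaces each bin by the mean of the bins within `window / 2` bases on
#' either side (clipped at chromosome ends).  Used to regularize a sparse
#' control track before input normalization: the input is expected to be
#' locally flat, so its local mean is a far better estimate of the
#' background rate than a single bin's count — the same reasoning behind
#' local-lambda background models in peak callers.
#'
#' @param track [density_track()].
#' @param window smoothing window in bases (default 5000).
#' @return smoothed [density_track()].
#' @export
smooth_track <- function(track, window = 5000) {
  half <- max(0L, as.integer(round(window / (2 * track$bin_width))))
  if (half == 0) return(track)
  values <- lapply(track$values, function(v) {
    n <- length(v)
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  density_track(values, bin_width = track$bin_width,
                library_size = track$library_size, sizes = track$sizes,
                mode = track$mode, name = track$name)
}

#' Genome-wide median of a track
#' @param track [density_track()].
#' @return median over all bins of all chromosomes.
#' @export
track_median <- function(track) {
  stats::median(unlist(track$values, use.names = FALSE))
}

# Rolling sums of window_bins consecutive bins (one value per start bin;
# trailing windows are truncated at the chromosome end).
rolling_window_sums <- function(v, window_bins) {
  cs <- c(0, cumsum(v))
  n <- length(v)
  ends <- pmin(seq_len(n) + window_bins - 1, n)
  cs[ends + 1] - cs[seq_len(n)]
}

#' Call peaks of local enrichment
#'
#' A simplified sliding-window caller standing in for MACS: fixed-width
#' windows (default 500 bp, stepped by one bin) are tested against the
#' depth-scaled control.  A window qualifies when its summed chip signal
#' exceeds both `mfold` times the local control expectation and a
#' one-sided Poisson upper-tail test at `alpha` against the local control
#' rate; the local rate is floored by the genome-wide control rate.
#' Qualifying windows are merged when they overlap or are adjacent; each
#' merged region reports the left-most maximal bin as its summit, and the
#' fold enrichment and Poisson p-value of the best window covering the
#' summit.  Unlike MACS there is no duplicate-read filtering, no fragment
#' shifting model and no dynamic band width; externally produced BED peak
#' lists can be used interchangeably downstream.
#'
#' @param chip,control raw [density_track()]s (layout-compatible).
#' @param window window width in bases (default 500).
#' @param mfold minimal fold enrichment over the control expectation
#'   (default 12, matching common practice for sharp acetylation marks).
#' @param alpha Poisson tail significance threshold in (0, 1), default 1e-5.
#' @return data.frame of class `peak_calls` with columns `chrom`, `start`,
#'   `end`, `summit`, `fold_enrichment`, `p_value`, `name`.
#' @export
call_peaks <- function(chip, control, window = 500, mfold = 12,
                       alpha = 1e-5) {
  abort_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  abort_if(window < chip$bin_width, "window smaller than one bin")
  check_compatible(chip, control)
  bw <- chip$bin_width
  wb <- max(1L, as.integer(round(window / bw)))
  depth_ratio <- if (!is.na(chip$library_size) && !is.na(control$library_size) &&
                     control$library_size > 0) {
    chip$library_size / control$library_size
  } else 1
  ctrl_all <- unlist(control$values, use.names = FALSE)
  global_rate <- mean(ctrl_all) * depth_ratio  # per bin
  out <- list()
  for (chrom in names(chip$values)) {
    cv <- chip$values[[chrom]]
    if (length(cv) == 0 || all(cv == 0)) next
    chip_ws <- rolling_window_sums(cv, wb)
    ctrl_ws <- rolling_window_sums(control$values[[chrom]], wb) * depth_ratio
    lambda <- pmax(ctrl_ws, global_rate * wb, 1e-9)
    q <- floor(chip_ws)
    pvals <- stats::ppois(q - 1, lambda, lower.tail = FALSE)
    hit <- chip_ws >= mfold * lambda & pvals < alpha & chip_ws > 0
    if (!any(hit)) next
    idx <- which(hit)
    # merge overlapping/adjacent qualifying windows (in bin units)
    w_start <- idx
    w_end <- pmin(idx + wb - 1, length(cv))
    brk <- c(TRUE, w_start[-1] > utils::head(w_end, -1) + 1)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      sel <- idx[grp == g]
      r_start <- sel[1]
      r_end <- min(sel[length(sel)] + wb - 1, length(cv))
      seg <- cv[r_start:r_end]
      summit_bin <- r_start + which.max(seg) - 1  # left-most maximum
      covering <- sel[sel <= summit_bin & (sel + wb - 1) >= summit_bin]
      best <- covering[which.min(pvals[covering])]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom,
        start = (r_start - 1) * bw,
        end = min(r_end * bw, chip$sizes[[chrom]] %||% (r_end * bw)),
        summit = (summit_bin - 1) * bw + floor(bw / 2),
        fold_enrichment = chip_ws[best] / lambda[best],
        p_value = max(pvals[best], .Machine$double.xmin),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), summit = numeric(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      name = character(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res$name <- sprintf("peak_%d", seq_len(nrow(res)))
  }
  class(res) <- c("peak_calls", "data.frame")
  res
}

#' Write peak calls as BED6 plus -log10(p)
#'
#' Fold enrichment goes in the score column; `-log10(p_value)` is appended
#' as column 7.
#'
#' @param peaks `peak_calls`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, format_coord(peaks$start),
                    format_coord(peaks$end), peaks$name,
                    signif(peaks$fold_enrichment, 6), ".",
                    signif(-log10(peaks$p_value), 6))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED peak list (e.g. produced by an external caller)
#'
#' @param path BED file; column 5 (when present) is taken as fold
#'   enrichment and column 7 as `-log10(p)`.
#' @return `peak_calls` with summit at the interval midpoint when no
#'   summit information is available.
#' @export
read_peaks <- function(path) {
  x <- read_bed(path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          data.table = FALSE)
  p <- if (ncol(dt) >= 7) 10^(-as.numeric(dt[[7]])) else rep(NA_real_, nrow(x))
  res <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    summit = floor((x$start + x$end) / 2),
                    fold_enrichment = ifelse(is.na(x$score), 0, x$score),
                    p_value = p,
                    name = ifelse(is.na(x$name),
                                  sprintf("peak_%d", seq_len(nrow(x))),
                                  x$name),
                    stringsAsFactors = FALSE)
  class(res) <- c("peak_calls", "data.frame")
  res
}

#' Tag density around reference sites
#'
#' The enrichment value at a binding site: the number of (extended) reads
#' present in, or overlapping, the window `[anchor - flank, anchor +
#' flank)` around each reference locus, plus its per-million-normalized
#' form.  When computed from a binned track instead of reads, the sum of
#' bin values intersecting the window is used; because raw bins hold
#' max-overlap values this track mode is an approximation of the read
#' count and is labelled as such in the result.
#'
#' @param reads_or_track extended reads ([genomic_intervals()]) or a
#'   [density_track()].
#' @param loci [reference_loci()] anchors.
#' @param flank half-window in bases (> 0); the study's enrichment windows
#'   are 3000 bp around the TSS, i.e. `flank = 1500`.
#' @param sizes [chrom_sizes()] (required for anchors bound checking).
#' @param library_size read count used for per-million scaling; defaults
#'   to the track's library size or the number of reads supplied.
#' @return data.frame `locus_id`, `count`, `normalized`, with attribute
#'   `mode` = `"reads"` or `"track"`.
#' @export
tag_density <- function(reads_or_track, loci, flank, sizes,
                        library_size = NULL) {
  abort_if(flank <= 0, "flank must be positive")
  lim <- unname(sizes[loci$chrom])
  abort_if(any(is.na(lim)) || any(loci$anchor < 0) || any(loci$anchor >= lim),
           "anchor outside chromosome bounds")
  w_start <- pmax(loci$anchor - flank, 0)
  w_end <- pmin(loci$anchor + flank, lim)
  if (inherits(reads_or_track, "density_track")) {
    track <- reads_or_track
    library_size <- library_size %||% track$library_size
    bw <- track$bin_width
    count <- numeric(nrow(loci))
    for (chrom in unique(loci$chrom)) {
      sel <- which(loci$chrom == chrom)
      v <- track$values[[chrom]]
      abort_if(is.null(v), "track lacks chromosome ", chrom)
      cs <- c(0, cumsum(v))
      b0 <- pmin(floor(w_start[sel] / bw), length(v) - 1)
      b1 <- pmin(ceiling(w_end[sel] / bw), length(v))
      count[sel] <- cs[b1 + 1] - cs[b0 + 1]
    }
    mode <- "track"
  } else {
    reads <- reads_or_track
    library_size <- library_size %||% nrow(reads)
    count <- numeric(nrow(loci))
    for (chrom in unique(loci$chrom)) {
      sel <- which(loci$chrom == chrom)
      rsel <- reads$chrom == chrom
      count[sel] <- IRanges::countOverlaps(
        as_iranges0(w_start[sel], w_end[sel]),
        as_iranges0(reads$start[rsel], reads$end[rsel]))
    }
    mode <- "reads"
  }
  res <- data.frame(locus_id = loci$locus_id, count = count,
                    normalized = count * 1e6 / library_size,
                    stringsAsFactors = FALSE)
  attr(res, "mode") <- mode
  res
}
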
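# Shared fixtures: tiny genomes, random interval sets and brute-force
# oracles kept independent of the implementation paths they check.

toy_sizes <- function(...) {
  v <- c(...)
  if (length(v) == 0) v <- c(chr1 = 10000)
  chrom_sizes(v)
}

make_track <- function(values, bin_width = 25, library_size = 100,
                       sizes = NULL, mode = "raw") {
  if (!is.list(values)) values <- list(chr1 = values)
  if (is.null(sizes)) {
    sizes <- chrom_sizes(vapply(values, function(v) length(v) * bin_width,
                                numeric(1)))
  }
  density_track(values, bin_width = bin_width, library_size = library_size,
                sizes = sizes, mode = mode)
}

random_reads <- function(n, sizes, max_len = 300) {
  chrom <- sample(names(sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * pmax(1, unname(sizes[chrom]) - len))
  genomic_intervals(chrom, start, start + len,
                    strand = sample(c("+", "-"), n, replace = TRUE))
}

# Brute-force per-base max-overlap binning: the oracle for bin_density.
brute_force_bins <- function(reads, bin_width, sizes) {
  lapply(stats::setNames(names(sizes), names(sizes)), function(chrom) {
    len <- sizes[[chrom]]
    depth <- integer(len)
    sel <- which(reads$chrom == chrom)
    for (i in sel) {
      idx <- (reads$start[i] + 1):reads$end[i]
      depth[idx] <- depth[idx] + 1L
    }
    n_bins <- ceiling(len / bin_width)
    vapply(seq_len(n_bins), function(b) {
      lo <- (b - 1) * bin_width + 1
      hi <- min(b * bin_width, len)
      max(depth[lo:hi])
    }, numeric(1))
  })
}

# Non-overlapping random gene models on the given genome.
random_genes <- function(n, sizes, min_len = 500, max_len = 3000,
                        gap = 500) {
  slots <- do.call(rbind, lapply(names(sizes), function(chrom) {
    k <- floor(sizes[[chrom]] / (max_len + gap))
    if (k == 0) return(NULL)
    data.frame(chrom = chrom, origin = (seq_len(k) - 1) * (max_len + gap))
  }))
  stopifnot(nrow(slots) >= n)
  slots <- slots[sample(nrow(slots), n), , drop = FALSE]
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- slots$origin + sample(0:gap, n, replace = TRUE)
  gene_models(sprintf("g%03d", seq_len(n)), slots$chrom,
              sample(c("+", "-"), n, replace = TRUE), start, start + len)
}

# Small fast generator spec used by several tests.
small_spec <- function(seed = 1, ...) {
  synthetic_spec(seed = seed,
                 chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                 genes = c(active = 14, bivalent = 8, inactive = 14,
                           primed = 8),
                 enhancers = c(active = 10, poised = 10),
                 ...)
}
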
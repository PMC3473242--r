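#' Genomic intervals
#'
#' The pipeline's universal coordinate unit: a data frame of genomic spans
#' in 0-based half-open convention (`start` inclusive, `end` exclusive),
#' the same convention as BED.  Coordinates are converted to other
#' conventions (1-based WIG) only at format boundaries.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval (recycled).
#' @param name optional labels.
#' @param score optional numeric scores.
#' @return a `data.frame` with class `genomic_intervals` and columns
#'   `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = ".",
                              name = NA_character_, score = NA_real_) {
  n <- length(chrom)
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

validate_intervals <- function(x, context = "intervals") {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  abort_if(length(bad) > 0,
           context, ": invalid coordinates (need 0 <= start < end) at record(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  badstr <- which(!x$strand %in% c("+", "-", "."))
  abort_if(length(badstr) > 0,
           context, ": invalid strand at record(s) ",
           paste(utils::head(badstr, 5), collapse = ", "))
  invisible(x)
}

#' Chromosome sizes
#'
#' Named lengths of the chromosomes every interval must fit inside.
#'
#' @param lengths named numeric vector, chromosome name -> length in bases.
#' @return a named integer-valued numeric vector of class `chrom_sizes`.
#' @export
chrom_sizes <- function(lengths) {
  abort_if(is.null(names(lengths)) || any(names(lengths) == ""),
           "chrom_sizes: every chromosome needs a name")
  abort_if(any(lengths <= 0) || any(lengths != floor(lengths)),
           "chrom_sizes: lengths must be positive integers")
  abort_if(anyDuplicated(names(lengths)) > 0,
           "chrom_sizes: duplicated chromosome names")
  structure(as.numeric(lengths), names = names(lengths),
            class = "chrom_sizes")
}

#' Check intervals against chromosome bounds
#'
#' Chromosome names are compared as exact strings; no aliasing such as
#' stripping a "chr" prefix is performed.
#'
#' @param x `genomic_intervals`.
#' @param sizes `chrom_sizes`.
#' @return `x` invisibly; errors if any interval lies outside its chromosome
#'   or names an unknown chromosome.
#' @export
check_bounds <- function(x, sizes) {
  unknown <- setdiff(unique(x$chrom), names(sizes))
  abort_if(length(unknown) > 0,
           "unknown chromosome(s): ", paste(unknown, collapse = ", "))
  len <- unname(sizes[x$chrom])
  abort_if(any(x$end > len),
           "interval(s) extend beyond chromosome end")
  invisible(x)
}

# Effective strand for direction-dependent operations: "." is treated as
# "+" with a warning, so degenerate input does not abort a run.
effective_strand <- function(strand) {
  dot <- strand == "."
  if (any(dot)) {
    warning(sum(dot), " interval(s) with strand '.'; treated as '+'",
            call. = FALSE)
    strand[dot] <- "+"
  }
  strand
}

#' Gene models
#'
#' A minimal refFlat-like gene table: one row per transcript with its span
#' and exon structure.  The TSS of a `+` gene is `start`; of a `-` gene it
#' is `end - 1` (the last covered base).
#'
#' @param gene_id character ids (unique).
#' @param chrom,strand,start,end transcript span; strand must be `+` or `-`.
#' @param exon_starts,exon_ends lists of integer vectors, one per gene;
#'   exons must be sorted, non-overlapping and contained in `[start, end)`.
#' @return a `data.frame` of class `gene_models` with a list column per
#'   exon boundary set.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        exon_starts = NULL, exon_ends = NULL) {
  n <- length(gene_id)
  if (is.null(exon_starts)) exon_starts <- as.list(start)
  if (is.null(exon_ends)) exon_ends <- as.list(end)
  abort_if(anyDuplicated(gene_id) > 0, "gene_models: duplicated gene ids")
  abort_if(!all(strand %in% c("+", "-")),
           "gene_models: strand must be '+' or '-'")
  abort_if(any(start < 0) || any(end <= start),
           "gene_models: need 0 <= start < end")
  for (i in seq_len(n)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    abort_if(length(es) != length(ee),
             "gene ", gene_id[i], ": exon starts/ends length mismatch")
    abort_if(any(ee <= es), "gene ", gene_id[i], ": inverted exon")
    abort_if(is.unsorted(es, strictly = TRUE) && length(es) > 1,
             "gene ", gene_id[i], ": exons not sorted")
    abort_if(length(es) > 1 && any(es[-1] < ee[-length(ee)]),
             "gene ", gene_id[i], ": overlapping exons")
    abort_if(es[1] < start[i] || ee[length(ee)] > end[i],
             "gene ", gene_id[i], ": exon outside transcript span")
  }
  x <- data.frame(gene_id = as.character(gene_id),
                  chrom = as.character(chrom),
                  strand = as.character(strand),
                  start = as.numeric(start), end = as.numeric(end),
                  stringsAsFactors = FALSE)
  x$exon_starts <- lapply(exon_starts, as.numeric)
  x$exon_ends <- lapply(exon_ends, as.numeric)
  class(x) <- c("gene_models", "data.frame")
  x
}

#' Transcription start sites of gene models
#'
#' @param genes `gene_models`.
#' @return numeric vector of 0-based TSS positions (`start` for `+`,
#'   `end - 1` for `-`).
#' @export
tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' Reference loci
#'
#' An ordered set of anchor points (e.g. TSSs or enhancer midpoints) used
#' for tag-density windows, profile matrices and classification.
#'
#' @param locus_id unique character ids.
#' @param chrom chromosome names.
#' @param anchor 0-based anchor base.
#' @param strand `+`, `-` or `.` (recycled).
#' @return data.frame of class `reference_loci`.
#' @export
reference_loci <- function(locus_id, chrom, anchor, strand = "+") {
  abort_if(anyDuplicated(locus_id) > 0, "reference_loci: duplicated ids")
  x <- data.frame(locus_id = as.character(locus_id),
                  chrom = as.character(chrom),
                  anchor = as.numeric(anchor),
                  strand = rep_len(as.character(strand), length(locus_id)),
                  stringsAsFactors = FALSE)
  abort_if(!all(x$strand %in% c("+", "-", ".")),
           "reference_loci: invalid strand")
  class(x) <- c("reference_loci", "data.frame")
  x
}

#' TSS reference loci of a gene table
#'
#' @param genes `gene_models`.
#' @return `reference_loci` anchored at each gene's TSS.
#' @export
tss_loci <- function(genes) {
  reference_loci(genes$gene_id, genes$chrom, tss(genes), genes$strand)
}
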
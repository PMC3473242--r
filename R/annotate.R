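# Genome partition into gene features and peak-to-feature assignment.

FEATURE_CLASSES <- c("promoter", "coding_exon", "intron",
                     "downstream_2kb", "distal_intergenic")

# per-chromosome IRanges list for one feature's genomic_intervals
feature_ranges <- function(x, chroms) {
  out <- lapply(chroms, function(chrom) {
    sel <- x$chrom == chrom
    as_iranges0(x$start[sel], x$end[sel])
  })
  names(out) <- chroms
  out
}

ranges_to_intervals <- function(rl) {
  parts <- lapply(names(rl), function(chrom) {
    ir <- rl[[chrom]]
    if (length(ir) == 0) return(NULL)
    cbind(data.frame(chrom = chrom, stringsAsFactors = FALSE),
          from_iranges0(ir))
  })
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0) {
    return(genomic_intervals())
  }
  df <- do.call(rbind, parts)
  genomic_intervals(df$chrom, df$start, df$end)
}

#' Partition the genome into gene features
#'
#' Every base of every chromosome is assigned to exactly one of five
#' classes: promoter (`promoter_up` bases upstream of the TSS,
#' strand-oriented), coding exon (union of annotated exons), intron (gene
#' body minus exons), downstream (2 kb past the 3' end), or distal
#' intergenic (everything else).  Overlaps between classes are resolved by
#' the precedence promoter > exon > intron > downstream > intergenic, so
#' the classes are mutually disjoint and jointly cover the genome
#' base-exactly.
#'
#' @param genes [gene_models()]; an empty table yields an all-intergenic
#'   partition with a warning.
#' @param sizes [chrom_sizes()].
#' @param promoter_up promoter extent upstream of the TSS (default 2000).
#' @param downstream downstream extent past the 3' end (default 2000).
#' @return object of class `feature_partition`: named list of
#'   `genomic_intervals` per class, plus the `chrom_sizes`.
#' @export
build_partition <- function(genes, sizes, promoter_up = 2000,
                            downstream = 2000) {
  chroms <- names(sizes)
  if (nrow(genes) == 0) {
    warning("empty gene list: whole genome classified distal_intergenic",
            call. = FALSE)
  }
  plus <- genes$strand == "+"
  t <- tss(genes)
  clamp <- function(s, e, chrom) {
    lim <- unname(sizes[chrom])
    data.frame(chrom = chrom, start = pmax(s, 0), end = pmin(e, lim))
  }
  prom <- clamp(ifelse(plus, t - promoter_up, t + 1),
                ifelse(plus, t, t + 1 + promoter_up), genes$chrom)
  dnst <- clamp(ifelse(plus, genes$end, genes$start - downstream),
                ifelse(plus, genes$end + downstream, genes$start),
                genes$chrom)
  ex <- data.frame(
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts) %||% numeric(0),
    end = unlist(genes$exon_ends) %||% numeric(0))
  body <- data.frame(chrom = genes$chrom, start = genes$start,
                     end = genes$end)
  drop_empty <- function(df) df[df$end > df$start, , drop = FALSE]
  layers <- lapply(list(prom, ex, body, dnst, body),
                   function(df) feature_ranges(drop_empty(df), chroms))
  features <- list()
  claimed <- lapply(chroms, function(chrom) IRanges::IRanges())
  names(claimed) <- chroms
  add_layer <- function(layer, claimed) {
    res <- lapply(chroms, function(chrom) {
      r <- IRanges::reduce(layer[[chrom]])
      IRanges::setdiff(r, claimed[[chrom]])
    })
    names(res) <- chroms
    res
  }
  union_into <- function(claimed, layer) {
    res <- lapply(chroms, function(chrom) {
      IRanges::union(claimed[[chrom]], layer[[chrom]])
    })
    names(res) <- chroms
    res
  }
  # promoter
  features$promoter <- add_layer(layers[[1]], claimed)
  claimed <- union_into(claimed, features$promoter)
  # coding exon
  features$coding_exon <- add_layer(layers[[2]], claimed)
  claimed <- union_into(claimed, features$coding_exon)
  # intron = gene body minus exons minus higher classes
  intron_layer <- lapply(chroms, function(chrom) {
    IRanges::setdiff(IRanges::reduce(layers[[3]][[chrom]]),
                     IRanges::reduce(layers[[2]][[chrom]]))
  })
  names(intron_layer) <- chroms
  features$intron <- add_layer(intron_layer, claimed)
  claimed <- union_into(claimed, features$intron)
  # downstream
  features$downstream_2kb <- add_layer(layers[[4]], claimed)
  claimed <- union_into(claimed, features$downstream_2kb)
  # intergenic = complement
  features$distal_intergenic <- lapply(chroms, function(chrom) {
    IRanges::setdiff(IRanges::IRanges(1, sizes[[chrom]]), claimed[[chrom]])
  })
  names(features$distal_intergenic) <- chroms
  out <- lapply(features, ranges_to_intervals)
  structure(list(features = out, sizes = sizes),
            class = "feature_partition")
}

#' Total bases per feature class
#' @param partition `feature_partition`.
#' @return named numeric vector of base-pair totals per class.
#' @export
partition_bp <- function(partition) {
  vapply(partition$features,
         function(x) sum(x$end - x$start), numeric(1))
}

#' Distribute peaks over genome features
#'
#' Each peak is assigned to the feature class containing its summit
#' (single assignment, so fractions sum to 1); with `rule =
#' "any_overlap"` a peak is instead counted once in every class its span
#' overlaps, the multi-count reporting style of genome-annotation tools.
#'
#' @param peaks `peak_calls`.
#' @param partition `feature_partition` covering the peaks' chromosomes.
#' @param rule `"summit"` (default) or `"any_overlap"`.
#' @return data.frame of class `peak_distribution` with one row per
#'   feature class: `peak_count`, `peak_fraction`, `genome_bp`,
#'   `genome_fraction`, `enrichment_ratio`; the per-peak assignment is
#'   attached as attribute `assignment` (summit rule only).
#' @export
assign_peaks <- function(peaks, partition, rule = c("summit", "any_overlap")) {
  rule <- match.arg(rule)
  unknown <- setdiff(unique(peaks$chrom), names(partition$sizes))
  abort_if(length(unknown) > 0,
           "peak(s) on unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
  chroms <- names(partition$sizes)
  counts <- stats::setNames(numeric(length(FEATURE_CLASSES)), FEATURE_CLASSES)
  assignment <- rep(NA_character_, nrow(peaks))
  for (feat in FEATURE_CLASSES) {
    fr <- feature_ranges(partition$features[[feat]], chroms)
    for (chrom in unique(peaks$chrom)) {
      sel <- which(peaks$chrom == chrom)
      if (rule == "summit") {
        q <- as_iranges0(peaks$summit[sel], peaks$summit[sel] + 1)
        hit <- IRanges::countOverlaps(q, fr[[chrom]]) > 0
        assignment[sel[hit]] <- feat
        counts[feat] <- counts[feat] + sum(hit)
      } else {
        q <- as_iranges0(peaks$start[sel], peaks$end[sel])
        counts[feat] <- counts[feat] +
          sum(IRanges::countOverlaps(q, fr[[chrom]]) > 0)
      }
    }
  }
  gbp <- partition_bp(partition)
  total <- max(sum(counts), 1)
  res <- data.frame(feature = FEATURE_CLASSES,
                    peak_count = unname(counts),
                    peak_fraction = unname(counts) / total,
                    genome_bp = unname(gbp),
                    genome_fraction = unname(gbp) / sum(gbp),
                    stringsAsFactors = FALSE)
  res$enrichment_ratio <- res$peak_fraction / res$genome_fraction
  attr(res, "rule") <- rule
  if (rule == "summit") attr(res, "assignment") <- assignment
  class(res) <- c("peak_distribution", "data.frame")
  res
}

#' Select intergenic peaks by the minimum-overlap rule
#'
#' A peak is called intergenic when its total overlap with distal
#' intergenic intervals is at least `min_overlap` bases (boundary
#' included).  The selection is monotone: raising the threshold never
#' adds peaks.
#'
#' @param peaks `peak_calls`.
#' @param partition `feature_partition`.
#' @param min_overlap minimum total overlap in bases (default 500).
#' @return the qualifying subset of `peaks`.
#' @export
intergenic_peaks <- function(peaks, partition, min_overlap = 500) {
  abort_if(min_overlap <= 0, "min_overlap must be positive")
  inter <- partition$features$distal_intergenic
  keep <- logical(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == chrom)
    isel <- inter$chrom == chrom
    ir <- as_iranges0(inter$start[isel], inter$end[isel])
    q <- as_iranges0(peaks$start[sel], peaks$end[sel])
    hits <- IRanges::findOverlaps(q, ir)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(hits)], ir[S4Vectors::subjectHits(hits)]))
    tot <- tapply(ov, S4Vectors::queryHits(hits), sum)
    keep[sel[as.integer(names(tot))]] <- tot >= min_overlap
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(peaks)
  out
}

#' Combine two marks' peak sets over promoters
#'
#' The combined TSS list: the subset of promoters whose `[anchor - flank,
#' anchor + flank)` window is overlapped by at least one peak from either
#' mark (set union; each promoter appears at most once, in input order).
#'
#' @param peaks_by_mark list of one or more `peak_calls` tables.
#' @param promoters [reference_loci()] of promoter anchors (TSSs).
#' @param flank half-window around the anchor in bases.
#' @return the combined [reference_loci()] subset.
#' @export
combine_tss_peak_sets <- function(peaks_by_mark, promoters, flank) {
  abort_if(nrow(promoters) == 0, "empty promoter list")
  hit <- logical(nrow(promoters))
  for (peaks in peaks_by_mark) {
    for (chrom in unique(promoters$chrom)) {
      sel <- which(promoters$chrom == chrom)
      psel <- peaks$chrom == chrom
      if (!any(psel)) next
      w <- as_iranges0(pmax(promoters$anchor[sel] - flank, 0),
                       promoters$anchor[sel] + flank)
      hit[sel] <- hit[sel] | IRanges::countOverlaps(
        w, as_iranges0(peaks$start[psel], peaks$end[psel])) > 0
    }
  }
  out <- promoters[hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(promoters)
  out
}

#' Export a feature partition as BED6
#'
#' Feature class name goes in column 4.
#'
#' @param partition `feature_partition`.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  dfs <- lapply(FEATURE_CLASSES, function(feat) {
    x <- partition$features[[feat]]
    if (nrow(x) == 0) return(NULL)
    data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
               feat, 0, ".")
  })
  out <- do.call(rbind, Filter(Negate(is.null), dfs))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
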
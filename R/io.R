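#' Read a BED file of intervals
#'
#' BED3 or BED6; 0-based half-open coordinates are kept as-is.  Strand is
#' taken from field 6 when present, otherwise `"."`.  Malformed records
#' (non-integer coordinates, `start >= end`) raise an error naming the
#' offending line.  Unknown chromosomes are allowed at read time; they are
#' flagged when the intervals are joined with a [chrom_sizes()] object via
#' [check_bounds()].
#'
#' @param path BED file path.
#' @return [genomic_intervals()].
#' @export
read_bed <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (nrow(dt) == 0) return(genomic_intervals())
  abort_if(ncol(dt) < 3, "BED file ", path, ": fewer than 3 columns")
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0 | start >= end)
  abort_if(length(bad) > 0,
           "BED file ", path, ": malformed record at line ", bad[1])
  name <- if (ncol(dt) >= 4) dt[[4]] else NA_character_
  name[!is.na(name) & !nzchar(name)] <- NA_character_
  strand <- if (ncol(dt) >= 6) dt[[6]] else "."
  strand[is.na(strand) | !nzchar(strand)] <- "."  # short records in mixed files
  genomic_intervals(
    chrom = dt[[1]], start = start, end = end, name = name,
    score = if (ncol(dt) >= 5) suppressWarnings(as.numeric(dt[[5]])) else NA_real_,
    strand = strand
  )
}

#' Write intervals as BED
#'
#' Emits BED6 (or BED3 when neither names, scores nor strands are
#' informative).  Round-trips through [read_bed()] to identical intervals.
#'
#' @param x [genomic_intervals()].
#' @param path output file path.
#' @export
write_bed <- function(x, path) {
  bed3 <- all(is.na(x$name)) && all(is.na(x$score)) && all(x$strand == ".")
  if (bed3) {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  } else {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                      ifelse(is.na(x$name), ".", x$name),
                      ifelse(is.na(x$score), "0", format_coord(x$score)),
                      x$strand)
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write a density track as fixedStep WIG
#'
#' One `fixedStep` declaration per chromosome with `step = span = bin
#' width`.  WIG bodies are 1-based per the format standard, so the bin
#' starting at 0-based position `p` is written with `start = p + 1`; this
#' is the only place in the package where the shift is applied.
#'
#' @param track a [density_track()].
#' @param path output path.
#' @export
write_wig <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"",
                     track$name %||% "density"), con)
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (length(v) == 0) next
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       chrom, track$bin_width, track$bin_width), con)
    writeLines(format(v, scientific = FALSE, trim = TRUE, digits = 15), con)
  }
  invisible(path)
}

#' Read a fixedStep WIG file back into a density track
#'
#' Supports the dialect written by [write_wig()]: `start=1`, `step ==
#' span`.  Used for round-trip checks and to re-load persisted tracks.
#'
#' @param path WIG file path.
#' @param sizes optional [chrom_sizes()]; when given, per-chromosome bin
#'   vectors are padded with zeros to full chromosome length.
#' @param library_size stored read count (WIG does not carry it).
#' @return a [density_track()].
#' @export
read_wig <- function(path, sizes = NULL, library_size = NA_real_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track")]
  decl <- grep("^fixedStep", lines)
  abort_if(length(decl) == 0 && length(lines) > 0 && any(nzchar(lines)),
           "WIG file ", path, ": no fixedStep declaration")
  values <- list()
  bin_width <- NA_integer_
  ends <- c(decl[-1] - 1, length(lines))
  for (i in seq_along(decl)) {
    hdr <- lines[decl[i]]
    chrom <- sub(".*chrom=([^ ]+).*", "\\1", hdr)
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", hdr))
    span <- as.integer(sub(".*span=([0-9]+).*", "\\1", hdr))
    start <- as.integer(sub(".*start=([0-9]+).*", "\\1", hdr))
    abort_if(step != span || start != 1,
             "WIG file ", path, ": unsupported fixedStep layout")
    abort_if(!is.na(bin_width) && bin_width != step,
             "WIG file ", path, ": mixed bin widths")
    bin_width <- step
    body <- lines[seq(decl[i] + 1, ends[i])]
    values[[chrom]] <- as.numeric(body[nzchar(body)])
  }
  if (!is.null(sizes)) {
    for (chrom in names(sizes)) {
      n <- ceiling(sizes[[chrom]] / bin_width)
      v <- values[[chrom]] %||% numeric(0)
      values[[chrom]] <- c(v, numeric(max(0, n - length(v))))
    }
    values <- values[names(sizes)]
  }
  density_track(values, bin_width = bin_width, library_size = library_size,
                sizes = sizes)
}

#' Read a refFlat-like gene table
#'
#' Tab-delimited columns: gene id, chromosome, strand, txStart, txEnd,
#' comma-separated exon starts, comma-separated exon ends.  A mismatch in
#' exon start/end counts is a parse error.
#'
#' @param path gene table path.
#' @return [gene_models()].
#' @export
read_gene_table <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", data.table = FALSE)
  if (nrow(dt) == 0) {
    return(gene_models(character(), character(), character(),
                       numeric(), numeric(), list(), list()))
  }
  abort_if(ncol(dt) < 7, "gene table ", path, ": expected 7 columns")
  parse_list <- function(s) lapply(strsplit(s, ","), function(v) {
    as.numeric(v[nzchar(v)])
  })
  gene_models(gene_id = dt[[1]], chrom = dt[[2]], strand = dt[[3]],
              start = as.numeric(dt[[4]]), end = as.numeric(dt[[5]]),
              exon_starts = parse_list(dt[[6]]),
              exon_ends = parse_list(dt[[7]]))
}

#' Write gene models as a refFlat-like table
#' @param genes [gene_models()].
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  fmt <- function(l) vapply(l, function(v) {
    paste0(paste(format_coord(v), collapse = ","), ",")
  }, character(1))
  out <- data.frame(genes$gene_id, genes$chrom, genes$strand,
                    format_coord(genes$start), format_coord(genes$end),
                    fmt(genes$exon_starts), fmt(genes$exon_ends))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column expression table
#'
#' Tab-delimited `gene_id <TAB> expression`; expression values must be
#' non-negative.
#'
#' @param path table path.
#' @return named numeric vector, gene id -> expression level.
#' @export
read_expression_table <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (nrow(dt) == 0) return(structure(numeric(0), names = character(0)))
  vals <- as.numeric(dt[[2]])
  abort_if(any(is.na(vals)) || any(vals < 0),
           "expression table ", path, ": non-numeric or negative values")
  structure(vals, names = as.character(dt[[1]]))
}

#' Write an expression table
#' @param expr named numeric vector.
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  data.table::fwrite(data.frame(names(expr), unname(expr)), path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CpG-island table
#'
#' BED intervals with the number of CpG dinucleotides in the score column
#' (BED field 5).
#'
#' @param path BED file path.
#' @return `genomic_intervals` with `score` holding the CpG count.
#' @export
read_cpg_table <- function(path) {
  x <- read_bed(path)
  abort_if(nrow(x) > 0 && (any(is.na(x$score)) || any(x$score < 0)),
           "CpG table ", path, ": missing or negative CpG counts")
  x
}
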
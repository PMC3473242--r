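# Synthetic genome, annotation and ChIP-seq read generator with planted
# chromatin states, so every pipeline stage can be tested end-to-end
# against known ground truth.

#' Marks the generator knows how to simulate
#' @export
SYNTHETIC_MARKS <- c("H3K9ac", "H3K14ac", "H3K4me3", "H3K27me3", "PolII",
                     "H3K4me1", "H3K27ac", "H3")

#' Default enrichment folds per planted state and mark
#'
#' Rows are gene states (`active`, `bivalent`, `inactive`, `primed`) and
#' enhancer classes (`enh_active`, `enh_poised`); columns are marks.  A
#' fold of `f` plants an expected `f * amp_base` enrichment reads at the
#' locus.  Active promoters carry the acetylation marks, H3K4me3 and Pol
#' II; bivalent promoters H3K4me3 plus H3K27me3 with moderate
#' acetylation; primed inactive promoters carry H3K14ac but no H3K9ac;
#' active enhancers carry H3K27ac (and acetylation) on top of H3K4me1,
#' poised enhancers H3K4me1 alone.
#'
#' @return states x marks numeric matrix.
#' @export
default_folds <- function() {
  marks <- setdiff(SYNTHETIC_MARKS, "H3")
  m <- matrix(0, nrow = 6, ncol = length(marks),
              dimnames = list(c("active", "bivalent", "inactive", "primed",
                                "enh_active", "enh_poised"), marks))
  m["active", c("H3K9ac", "H3K14ac", "H3K4me3", "PolII")] <- c(10, 10, 12, 8)
  m["bivalent", c("H3K9ac", "H3K14ac", "H3K4me3", "H3K27me3")] <- c(3, 3, 8, 8)
  m["primed", "H3K14ac"] <- 3
  m["enh_active", c("H3K9ac", "H3K14ac", "H3K4me1", "H3K27ac")] <- c(4, 4, 8, 8)
  m["enh_poised", "H3K4me1"] <- 8
  m
}

#' Specification of a synthetic ChIP-seq study
#'
#' Collects every knob of the generator.  Defaults describe a small
#' two-chromosome toy genome whose planted structure mirrors the
#' statistical features the pipeline is meant to recover: bimodal
#' promoter enrichment with a nucleosome-depleted region (NDR) at the
#' TSS, inter-mark amplitude correlation, amplitude coupling to
#' expression and CpG content, bivalent promoters, primed inactive
#' promoters, and enhancers split by H3K27ac.
#'
#' @param seed integer master seed; every output is deterministic in it.
#' @param chrom_lengths named vector of chromosome lengths (default two
#'   2 Mb chromosomes).
#' @param genes gene counts per state, named `active`, `bivalent`,
#'   `inactive`, `primed`.
#' @param enhancers enhancer counts per class, named `active`, `poised`.
#' @param marks marks to simulate (subset of [SYNTHETIC_MARKS]).
#' @param background_rate per-mark uniform background, reads/kb.
#' @param input_rate input (control) library depth, reads/kb.
#' @param h3_rate total-H3 nucleosome track depth, reads/kb.
#' @param amp_base expected planted reads per unit fold.
#' @param folds states x marks fold matrix (see [default_folds()]).
#' @param bimodal_offset distance of the two promoter enrichment modes
#'   from the TSS in bases (default 200).
#' @param peak_sd s.d. of each enrichment mode in bases (default 150).
#' @param ndr_width width of the nucleosome-depleted region at the TSS
#'   from which enrichment fragments are excluded (default 150).
#' @param ndr_depletion probability that a total-H3 fragment falling in
#'   an active-promoter NDR is removed (default 0.85).
#' @param rho latent correlation of H3K9ac and H3K14ac amplitudes.
#' @param amp_sdlog log-s.d. of the shared latent amplitude factor for
#'   the two acetylation marks.
#' @param other_sdlog log-s.d. of amplitude noise for the other marks.
#' @param expr_slope exponent coupling amplitude to expression level.
#' @param cpg_slope exponent coupling amplitude to CpG count.
#' @param expr_meanlog,expr_sdlog log-normal expression distribution of
#'   active genes.
#' @param read_length sequenced read length in bases (default 27).
#' @param fragment_length theoretical fragment length the reads are later
#'   extended to (default 200).
#' @param gene_length_range min/max gene length in bases.
#' @param min_gap minimal gap between gene footprints (default 12000,
#'   leaving room for +/-5 kb profile windows).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1,
                           chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                           genes = c(active = 60, bivalent = 30,
                                     inactive = 60, primed = 30),
                           enhancers = c(active = 40, poised = 40),
                           marks = SYNTHETIC_MARKS,
                           background_rate = 5, input_rate = 5,
                           h3_rate = 25, amp_base = 30,
                           folds = default_folds(),
                           bimodal_offset = 200, peak_sd = 150,
                           ndr_width = 150, ndr_depletion = 0.85,
                           rho = 0.7, amp_sdlog = 0.8, other_sdlog = 0.3,
                           expr_slope = 0.5, cpg_slope = 0.3,
                           expr_meanlog = 3, expr_sdlog = 1.5,
                           read_length = 27, fragment_length = 200,
                           gene_length_range = c(1000, 3000),
                           min_gap = 12000) {
  abort_if(rho < -1 || rho > 1, "rho must be in [-1, 1]")
  abort_if(any(c(background_rate, input_rate, h3_rate, amp_base) < 0),
           "rates must be non-negative")
  abort_if(!all(names(genes) %in% c("active", "bivalent", "inactive",
                                    "primed")),
           "gene states must be active/bivalent/inactive/primed")
  abort_if(!all(marks %in% SYNTHETIC_MARKS),
           "unknown mark(s): ",
           paste(setdiff(marks, SYNTHETIC_MARKS), collapse = ", "))
  spec <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
               genes = genes, enhancers = enhancers, marks = marks,
               background_rate = background_rate, input_rate = input_rate,
               h3_rate = h3_rate, amp_base = amp_base, folds = folds,
               bimodal_offset = bimodal_offset, peak_sd = peak_sd,
               ndr_width = ndr_width, ndr_depletion = ndr_depletion,
               rho = rho, amp_sdlog = amp_sdlog, other_sdlog = other_sdlog,
               expr_slope = expr_slope, cpg_slope = cpg_slope,
               expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
               read_length = read_length, fragment_length = fragment_length,
               gene_length_range = gene_length_range, min_gap = min_gap)
  class(spec) <- "synthetic_spec"
  spec
}

#' Build the synthetic genome, annotation and planted truth
#'
#' Genes (and enhancers) are placed in randomly chosen, non-overlapping
#' slots so footprints never come closer than `min_gap`; states are
#' assigned by shuffling the requested counts.  Expression is log-normal
#' for active genes, low for bivalent and near zero for inactive ones;
#' CpG counts overlap across states but decrease from active to
#' inactive.  H3K9ac/H3K14ac amplitudes share a latent log-normal factor
#' with correlation `rho` and are multiplied by the state fold and by the
#' expression and CpG coupling factors (normalized within state, so a
#' state's mean amplitude stays `amp_base * fold`).
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_genome` with elements `sizes`
#'   ([chrom_sizes()]), `genes` ([gene_models()]), `cpg`
#'   (`genomic_intervals` with the CpG count in `score`), `expression`
#'   (named vector), `enhancers` ([reference_loci()]) and `truth` (the
#'   planted per-locus states and amplitudes).
#' @export
build_genome <- function(spec) {
  with_seed(spec$seed, build_genome_impl(spec))
}

build_genome_impl <- function(spec) {
  sizes <- chrom_sizes(spec$chrom_lengths)
  n_genes <- sum(spec$genes)
  n_enh <- sum(spec$enhancers)
  margin <- 6000  # keep +/-5 kb windows inside the chromosome
  slot_width <- max(spec$gene_length_range) + spec$min_gap
  slots <- do.call(rbind, lapply(names(sizes), function(chrom) {
    usable <- sizes[[chrom]] - 2 * margin
    k <- max(0, floor(usable / slot_width))
    if (k == 0) return(NULL)
    data.frame(chrom = chrom,
               origin = margin + (seq_len(k) - 1) * slot_width)
  }))
  abort_if(is.null(slots) || nrow(slots) < n_genes + n_enh,
           "genome too small for ", n_genes, " genes + ", n_enh,
           " enhancers at min_gap ", spec$min_gap)
  pick <- sample(nrow(slots), n_genes + n_enh)
  gene_slots <- slots[pick[seq_len(n_genes)], , drop = FALSE]
  enh_slots <- slots[pick[n_genes + seq_len(n_enh)], , drop = FALSE]

  # --- genes ---------------------------------------------------------
  if (n_genes > 0) {
    len <- round(stats::runif(n_genes, spec$gene_length_range[1],
                              spec$gene_length_range[2]))
    offset <- floor(stats::runif(n_genes) *
                      (slot_width - spec$min_gap - len + 1))
    start <- gene_slots$origin + offset
    end <- start + len
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    state <- sample(rep(names(spec$genes), spec$genes))
    exon_starts <- vector("list", n_genes)
    exon_ends <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      n_ex <- sample(1:3, 1)
      if (n_ex == 1) {
        exon_starts[[i]] <- start[i]; exon_ends[[i]] <- end[i]
      } else {
        cuts <- sort(sample(seq(start[i] + 50, end[i] - 50, by = 10),
                            2 * (n_ex - 1)))
        b <- c(start[i], cuts, end[i])
        exon_starts[[i]] <- b[seq(1, length(b) - 1, by = 2)]
        exon_ends[[i]] <- b[seq(2, length(b), by = 2)]
      }
    }
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    genes <- gene_models(gene_id, gene_slots$chrom, strand, start, end,
                         exon_starts, exon_ends)
    # expression by state
    expression <- numeric(n_genes)
    expression[state == "active"] <-
      stats::rlnorm(sum(state == "active"), spec$expr_meanlog,
                    spec$expr_sdlog)
    expression[state == "bivalent"] <-
      stats::rlnorm(sum(state == "bivalent"), 0, 0.5)
    idle <- state %in% c("inactive", "primed")
    expression[idle] <- stats::runif(sum(idle), 0, 0.01)
    names(expression) <- gene_id
    # CpG counts: active > bivalent > inactive on average, overlapping
    cpg_mean <- c(active = 80, bivalent = 45, inactive = 15, primed = 15)
    cpg_count <- stats::rpois(n_genes, cpg_mean[state])
    # latent amplitude factors for the acetylation marks
    z1 <- stats::rnorm(n_genes)
    z2 <- spec$rho * z1 + sqrt(1 - spec$rho^2) * stats::rnorm(n_genes)
    latent <- cbind(H3K9ac = exp(spec$amp_sdlog * z1 - spec$amp_sdlog^2 / 2),
                    H3K14ac = exp(spec$amp_sdlog * z2 - spec$amp_sdlog^2 / 2))
    # state-normalized coupling factors (geometric-mean centred)
    couple <- function(v, slope) {
      f <- (v + 1)^slope
      for (s in unique(state)) {
        sel <- state == s
        f[sel] <- f[sel] / exp(mean(log(f[sel])))
      }
      f
    }
    coupling <- couple(expression, spec$expr_slope) *
      couple(cpg_count, spec$cpg_slope)
    amp <- matrix(0, n_genes, ncol(spec$folds),
                  dimnames = list(gene_id, colnames(spec$folds)))
    for (m in colnames(spec$folds)) {
      fold <- spec$folds[state, m]
      noise <- if (m %in% c("H3K9ac", "H3K14ac")) {
        latent[, m] * coupling
      } else {
        exp(spec$other_sdlog * stats::rnorm(n_genes) -
              spec$other_sdlog^2 / 2)
      }
      amp[, m] <- spec$amp_base * fold * noise
    }
    gene_truth <- data.frame(gene_id = gene_id, chrom = gene_slots$chrom,
                             strand = strand, start = start, end = end,
                             tss = ifelse(strand == "+", start, end - 1),
                             state = state, expression = unname(expression),
                             cpg_count = cpg_count,
                             stringsAsFactors = FALSE)
    gene_truth <- cbind(gene_truth,
                        stats::setNames(as.data.frame(amp),
                                        paste0("amp_", colnames(amp))))
    cpg <- genomic_intervals(gene_slots$chrom,
                             pmax(gene_truth$tss - 500, 0),
                             gene_truth$tss + 500,
                             name = gene_id, score = cpg_count)
  } else {
    genes <- gene_models(character(), character(), character(),
                         numeric(), numeric(), list(), list())
    expression <- stats::setNames(numeric(0), character(0))
    cpg <- genomic_intervals()
    gene_truth <- data.frame()
  }

  # --- enhancers -----------------------------------------------------
  if (n_enh > 0) {
    e_anchor <- enh_slots$origin +
      floor((slot_width - spec$min_gap) / 2)
    e_class <- sample(rep(names(spec$enhancers), spec$enhancers))
    enh_id <- sprintf("e%04d", seq_len(n_enh))
    e_state <- paste0("enh_", e_class)
    e_amp <- matrix(0, n_enh, ncol(spec$folds),
                    dimnames = list(enh_id, colnames(spec$folds)))
    for (m in colnames(spec$folds)) {
      e_amp[, m] <- spec$amp_base * spec$folds[e_state, m] *
        exp(spec$other_sdlog * stats::rnorm(n_enh) -
              spec$other_sdlog^2 / 2)
    }
    enh_truth <- cbind(
      data.frame(enh_id = enh_id, chrom = enh_slots$chrom,
                 anchor = e_anchor, class = e_class,
                 stringsAsFactors = FALSE),
      stats::setNames(as.data.frame(e_amp), paste0("amp_", colnames(e_amp))))
    enhancers <- reference_loci(enh_id, enh_slots$chrom, e_anchor, ".")
  } else {
    enh_truth <- data.frame()
    enhancers <- reference_loci(character(), character(), numeric())
  }

  structure(list(sizes = sizes, genes = genes, cpg = cpg,
                 expression = expression, enhancers = enhancers,
                 truth = list(genes = gene_truth, enhancers = enh_truth)),
            class = "synthetic_genome")
}

# Draw reads whose 200 bp directional extension covers the given fragment
# centers, mimicking sequencing of fragment ends.
reads_from_centers <- function(centers, chrom, sizes, read_length,
                               fragment_length) {
  n <- length(centers)
  if (n == 0) return(genomic_intervals())
  strand <- sample(c("+", "-"), n, replace = TRUE)
  u <- stats::runif(n, 0, fragment_length)
  start <- ifelse(strand == "+", round(centers - u),
                  round(centers + u) - read_length)
  lim <- unname(sizes[chrom]) - read_length
  start <- pmax(0, pmin(start, lim))
  genomic_intervals(chrom, start, start + read_length, strand = strand)
}

uniform_reads <- function(rate_per_kb, sizes, read_length) {
  out <- lapply(names(sizes), function(chrom) {
    n <- stats::rpois(1, rate_per_kb * sizes[[chrom]] / 1000)
    if (n == 0) return(NULL)
    start <- floor(stats::runif(n, 0, sizes[[chrom]] - read_length))
    genomic_intervals(chrom, start, start + read_length,
                      strand = sample(c("+", "-"), n, replace = TRUE))
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) return(genomic_intervals())
  x <- do.call(rbind, out)
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

# Bimodal fragment centers around an anchor with NDR rejection sampling.
bimodal_centers <- function(n, anchor, offset, sd, ndr_width) {
  if (n == 0) return(numeric(0))
  draw <- function(k) {
    anchor + sample(c(-1, 1), k, replace = TRUE) * offset +
      stats::rnorm(k, 0, sd)
  }
  c_ <- draw(n)
  for (iter in 1:50) {
    bad <- abs(c_ - anchor) < ndr_width / 2
    if (!any(bad)) break
    c_[bad] <- draw(sum(bad))
  }
  c_
}

#' Simulate ChIP-seq reads for one mark
#'
#' Background reads are uniform Poisson; per-locus enrichment read counts
#' are Poisson with the planted amplitude from `genome$truth`.  Promoter
#' enrichment fragments follow a two-component Gaussian mixture at TSS
#' +/- `bimodal_offset` with the NDR excluded by rejection sampling;
#' enhancer fragments are unimodal at the anchor.  The special mark
#' `"H3"` is a uniform nucleosome track thinned inside active-promoter
#' NDRs.  Reads are `read_length` bases and mark fragment ends, so that
#' the standard 200 bp directional extension recovers the planted
#' fragment positions.  Deterministic given the spec seed and mark.
#'
#' @param spec [synthetic_spec()].
#' @param genome output of [build_genome()].
#' @param mark one of [SYNTHETIC_MARKS].
#' @return reads as [genomic_intervals()].
#' @export
simulate_mark_reads <- function(spec, genome, mark) {
  abort_if(!mark %in% SYNTHETIC_MARKS, "unknown mark: ", mark)
  with_seed(spec$seed + 131L * match(mark, SYNTHETIC_MARKS),
            simulate_mark_reads_impl(spec, genome, mark))
}

simulate_mark_reads_impl <- function(spec, genome, mark) {
  sizes <- genome$sizes
  if (mark == "H3") {
    bg <- uniform_reads(spec$h3_rate, sizes, spec$read_length)
    gt <- genome$truth$genes
    if (nrow(bg) > 0 && NROW(gt) > 0 && any(gt$state == "active")) {
      act <- gt[gt$state == "active", , drop = FALSE]
      centers <- (bg$start + bg$end) / 2
      half <- 300
      drop <- logical(nrow(bg))
      for (chrom in unique(act$chrom)) {
        sel <- bg$chrom == chrom
        asel <- act$chrom == chrom
        hit <- IRanges::countOverlaps(
          as_iranges0(floor(centers[sel]), floor(centers[sel]) + 1),
          as_iranges0(act$tss[asel] - half, act$tss[asel] + half)) > 0
        drop[sel][hit] <- TRUE
      }
      drop <- drop & stats::runif(nrow(bg)) < spec$ndr_depletion
      bg <- bg[!drop, , drop = FALSE]
      class(bg) <- c("genomic_intervals", "data.frame")
    }
    return(bg)
  }
  parts <- list(uniform_reads(spec$background_rate, sizes,
                              spec$read_length))
  gt <- genome$truth$genes
  if (NROW(gt) > 0) {
    amp <- gt[[paste0("amp_", mark)]]
    n_reads <- stats::rpois(nrow(gt), amp)
    keep <- n_reads > 0
    if (any(keep)) {
      centers <- unlist(Map(function(n, a) {
        bimodal_centers(n, a, spec$bimodal_offset, spec$peak_sd,
                        spec$ndr_width)
      }, n_reads[keep], gt$tss[keep]))
      chroms <- rep(gt$chrom[keep], n_reads[keep])
      parts[[length(parts) + 1]] <-
        reads_from_centers(centers, chroms, sizes, spec$read_length,
                           spec$fragment_length)
    }
  }
  et <- genome$truth$enhancers
  if (NROW(et) > 0) {
    amp <- et[[paste0("amp_", mark)]]
    n_reads <- stats::rpois(nrow(et), amp)
    keep <- n_reads > 0
    if (any(keep)) {
      centers <- unlist(Map(function(n, a) {
        a + stats::rnorm(n, 0, spec$peak_sd)
      }, n_reads[keep], et$anchor[keep]))
      chroms <- rep(et$chrom[keep], n_reads[keep])
      parts[[length(parts) + 1]] <-
        reads_from_centers(centers, chroms, sizes, spec$read_length,
                           spec$fragment_length)
    }
  }
  parts <- Filter(function(x) nrow(x) > 0, parts)
  if (length(parts) == 0) return(genomic_intervals())
  x <- do.call(rbind, parts)
  rownames(x) <- NULL
  class(x) <- c("genomic_intervals", "data.frame")
  x
}

#' Simulate input (control) reads
#'
#' Uniform background at the spec's input depth with no planted
#' enrichment anywhere.
#'
#' @param spec [synthetic_spec()].
#' @param genome output of [build_genome()] (for chromosome sizes).
#' @return reads as [genomic_intervals()].
#' @export
simulate_input_reads <- function(spec, genome) {
  with_seed(spec$seed + 997L,
            uniform_reads(spec$input_rate, genome$sizes, spec$read_length))
}

#' Run the whole generator and write its files
#'
#' Writes `genes.tsv`, `expression.tsv`, `cpg.bed`,
#' `reads/<mark>.bed` for every simulated mark, `reads/input.bed`,
#' `truth.json` and a `spec.yaml` echo of the generator settings.
#'
#' @param spec [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the [build_genome()] object, invisibly, with a `files`
#'   manifest attached.
#' @export
simulate_experiment <- function(spec, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE,
             showWarnings = FALSE)
  genome <- build_genome(spec)
  files <- c(genes = file.path(dir, "genes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             cpg = file.path(dir, "cpg.bed"),
             chrom_sizes = file.path(dir, "chrom.sizes"),
             truth = file.path(dir, "truth.json"),
             spec = file.path(dir, "spec.yaml"),
             input = file.path(dir, "reads", "input.bed"))
  write_gene_table(genome$genes, files["genes"])
  write_expression_table(genome$expression, files["expression"])
  write_bed(genome$cpg, files["cpg"])
  data.table::fwrite(data.frame(names(genome$sizes),
                                format_coord(unname(genome$sizes))),
                     files["chrom_sizes"], sep = "\t", col.names = FALSE,
                     quote = FALSE)
  for (mark in spec$marks) {
    f <- file.path(dir, "reads", paste0(mark, ".bed"))
    write_bed(simulate_mark_reads(spec, genome, mark), f)
    files[paste0("reads_", mark)] <- f
  }
  write_bed(simulate_input_reads(spec, genome), files["input"])
  jsonlite::write_json(genome$truth, files["truth"], digits = NA,
                       dataframe = "columns")
  spec_echo <- spec
  spec_echo$folds <- as.data.frame(spec_echo$folds)
  yaml::write_yaml(lapply(unclass(spec_echo), function(x) {
    if (is.data.frame(x)) lapply(x, identity) else x
  }), files["spec"])
  genome$files <- files
  invisible(genome)
}
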
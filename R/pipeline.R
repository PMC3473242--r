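# Run orchestration: ties the stages into reproducible workflows with a
# single config, explicit seeds and a hashed output manifest.

PIPELINE_STAGES <- c("simulate", "coverage", "peaks", "annotate",
                     "profiles", "classify", "correlate", "ratio")

#' Default run configuration
#'
#' Every stage parameter with its default: 200 bp read extension and
#' 25 bp max-overlap bins for density tracks; 500 bp windows, 12-fold
#' enrichment and Poisson alpha 1e-5 for peak calling; 2 kb promoters and
#' downstream regions with the 500 bp intergenic-overlap rule; +/-5 kb
#' profile windows in 100 bins (50 bp flank bins for gene-body
#' profiles); k = 3 promoter clusters and k = 4 enhancer clusters with a
#' 2x-median presence threshold; 1.5 kb tag-density windows, 2 kb
#' correlation windows; pseudocount 1 throughout.
#'
#' @return named list of parameters.
#' @export
default_run_config <- function() {
  list(
    out_dir = "chromstate_out",
    seed = 1L,
    simulate = NULL,            # list of synthetic_spec() arguments
    reads = NULL,               # named list mark -> BED path
    input = NULL,               # control BED path
    genes = NULL, expression = NULL, cpg = NULL, chrom_sizes = NULL,
    enhancer_loci = NULL,       # optional BED of enhancer anchors
    extension_length = 200, bin_width = 25, normalize_pseudocount = 1,
    control_smooth = 5000,
    peak_marks = c("H3K9ac", "H3K14ac"),
    peak_window = 500, mfold = 12, alpha = 1e-5,
    promoter_up = 2000, downstream = 2000,
    intergenic_min_overlap = 500, combine_flank = 2000,
    profile_flank = 5000, profile_bins = 100,
    body_bins = 100, flank_bin_width = 50,
    promoter_marks = c("H3K9ac", "H3K14ac", "H3K4me3", "H3K27me3",
                       "PolII"),
    enhancer_marks = c("H3K4me1", "H3K27ac", "H3K9ac", "H3K14ac"),
    k_promoter = 3, k_enhancer = 4, n_restarts = 10,
    presence_factor = 2,
    central_flank_promoter = 1000, central_flank_enhancer = 500,
    tag_flank = 1500, corr_flank = 2000,
    ratio_pseudocount = 1, n_primed = 500
  )
}

#' Read and validate a run configuration
#'
#' Merges a YAML file over [default_run_config()]; unknown keys are
#' rejected by name.
#'
#' @param path YAML config path, or a named list of overrides.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  overrides <- if (is.character(path)) yaml::read_yaml(path) else path
  config <- default_run_config()
  unknown <- setdiff(names(overrides), names(config))
  abort_if(length(unknown) > 0,
           "unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(config, overrides)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` ->
#' `coverage` -> `peaks` / `profiles` -> `annotate` -> `classify` ->
#' `correlate` -> `ratio`.  Inputs a requested stage needs must either be
#' configured as files or be produced by an earlier requested stage;
#' otherwise the run fails before any computation, listing the missing
#' artifacts.  Every output file gets a manifest entry (md5, stage,
#' parameters, seed) written to `manifest.json`; a rerun with identical
#' config and seed reproduces identical hashes.
#'
#' @param config list from [read_run_config()] / [default_run_config()].
#' @param stages character subset of the stage names (default: all).
#' @return invisible list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  abort_if(!all(stages %in% PIPELINE_STAGES),
           "unknown stage(s): ",
           paste(setdiff(stages, PIPELINE_STAGES), collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  check_stage_inputs(config, stages)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  manifest <- list(seed = config$seed,
                   parameters = config[!vapply(config, is.null,
                                               logical(1))],
                   files = list())
  record <- function(path, stage) {
    manifest$files[[basename(path)]] <<-
      list(stage = stage, md5 = unname(tools::md5sum(path)))
  }

  if ("simulate" %in% stages) {
    spec <- do.call(synthetic_spec,
                    c(list(seed = config$seed), config$simulate))
    genome <- simulate_experiment(spec, file.path(out_dir, "sim"))
    st$genome <- genome
    st$spec <- spec
    config$reads <- as.list(genome$files[paste0("reads_", spec$marks)])
    names(config$reads) <- spec$marks
    config$input <- genome$files[["input"]]
    config$genes <- genome$files[["genes"]]
    config$expression <- genome$files[["expression"]]
    config$cpg <- genome$files[["cpg"]]
    for (f in genome$files) record(f, "simulate")
  }

  if (any(c("coverage", "peaks", "profiles", "classify", "correlate",
            "ratio") %in% stages)) {
    st$sizes <- if (!is.null(st$genome)) st$genome$sizes else
      read_chrom_sizes(config$chrom_sizes)
    st$genes <- if (!is.null(st$genome)) st$genome$genes else
      read_gene_table(config$genes)
  }

  if ("coverage" %in% stages) {
    input_reads <- extend_reads(read_bed(config$input),
                                config$extension_length, st$sizes)
    st$input_track <- bin_density(input_reads, config$bin_width, st$sizes)
    st$smoothed_input <- smooth_track(st$input_track, config$control_smooth)
    st$tracks <- list()
    st$norm_tracks <- list()
    st$ext_reads <- list()
    for (mark in names(config$reads)) {
      ext <- extend_reads(read_bed(config$reads[[mark]]),
                          config$extension_length, st$sizes)
      st$ext_reads[[mark]] <- ext
      tr <- bin_density(ext, config$bin_width, st$sizes)
      tr$name <- mark
      st$tracks[[mark]] <- tr
      st$norm_tracks[[mark]] <-
        normalize_to_input(tr, st$smoothed_input,
                           config$normalize_pseudocount)
      wig <- file.path(out_dir, paste0(mark, ".wig"))
      write_wig(tr, wig)
      record(wig, "coverage")
    }
  }

  if ("peaks" %in% stages) {
    st$peaks <- list()
    for (mark in intersect(config$peak_marks, names(st$tracks))) {
      pk <- call_peaks(st$tracks[[mark]], st$input_track,
                       window = config$peak_window, mfold = config$mfold,
                       alpha = config$alpha)
      st$peaks[[mark]] <- pk
      f <- file.path(out_dir, paste0(mark, "_peaks.bed"))
      write_peaks(pk, f)
      record(f, "peaks")
    }
  }

  if ("annotate" %in% stages) {
    st$partition <- build_partition(st$genes, st$sizes,
                                    config$promoter_up, config$downstream)
    f <- file.path(out_dir, "partition.bed")
    write_partition(st$partition, f)
    record(f, "annotate")
    st$distributions <- list()
    st$intergenic <- list()
    for (mark in names(st$peaks)) {
      dist <- assign_peaks(st$peaks[[mark]], st$partition)
      st$distributions[[mark]] <- dist
      f <- file.path(out_dir, paste0(mark, "_feature_distribution.tsv"))
      data.table::fwrite(as.data.frame(dist), f, sep = "\t", quote = FALSE)
      record(f, "annotate")
      st$intergenic[[mark]] <-
        intergenic_peaks(st$peaks[[mark]], st$partition,
                         config$intergenic_min_overlap)
    }
    st$combined_tss <- combine_tss_peak_sets(st$peaks, tss_loci(st$genes),
                                             config$combine_flank)
    f <- file.path(out_dir, "combined_tss.tsv")
    data.table::fwrite(st$combined_tss, f, sep = "\t", quote = FALSE)
    record(f, "annotate")
  }

  if (any(c("profiles", "classify") %in% stages)) {
    loci <- tss_loci(st$genes)
    st$tss_matrices <- lapply(st$norm_tracks, collect_tss_matrix, loci,
                              config$profile_flank, config$profile_bins)
  }

  if ("profiles" %in% stages) {
    for (mark in names(st$tss_matrices)) {
      prof <- average_profile(st$tss_matrices[[mark]])
      f <- file.path(out_dir, paste0(mark, "_tss_profile.tsv"))
      write_profile(prof, f)
      record(f, "profiles")
    }
  }

  if ("classify" %in% stages) {
    pm <- intersect(config$promoter_marks, names(st$tss_matrices))
    mmm <- multi_mark_matrix(st$tss_matrices[pm])
    st$promoter_clusters <- kmeans_cluster(mmm, config$k_promoter,
                                           seed = config$seed,
                                           n_restarts = config$n_restarts)
    # background per mark: median of the locally averaged ratio, the
    # same windowed-mean statistic the presence rule thresholds
    backgrounds <- vapply(st$norm_tracks[pm], function(t) {
      track_median(smooth_track(t, config$control_smooth))
    }, numeric(1))
    st$promoter_classes <- classify_promoters(
      st$promoter_clusters,
      mark_summaries(mmm, config$central_flank_promoter),
      backgrounds, config$presence_factor)
    f <- file.path(out_dir, "promoter_classes.tsv")
    data.table::fwrite(st$promoter_classes, f, sep = "\t", quote = FALSE)
    record(f, "classify")
    enh <- enhancer_loci_for(config, st)
    if (!is.null(enh) && nrow(enh) > 0 &&
        "H3K27ac" %in% names(st$norm_tracks)) {
      k27 <- collect_tss_matrix(st$norm_tracks[["H3K27ac"]], enh,
                                config$profile_flank, config$profile_bins)
      st$enhancer_classes <- classify_enhancers(
        enh, k27,
        track_median(smooth_track(st$norm_tracks[["H3K27ac"]],
                                  config$control_smooth)),
        config$presence_factor, config$central_flank_enhancer)
      f <- file.path(out_dir, "enhancer_classes.tsv")
      data.table::fwrite(st$enhancer_classes, f, sep = "\t", quote = FALSE)
      record(f, "classify")
    }
  }

  if (any(c("correlate", "ratio") %in% stages)) {
    loci <- tss_loci(st$genes)
    st$tag_densities <- vapply(names(st$ext_reads), function(mark) {
      tag_density(st$ext_reads[[mark]], loci, config$corr_flank,
                  st$sizes)$normalized
    }, numeric(nrow(loci)))
    rownames(st$tag_densities) <- loci$locus_id
  }

  if ("correlate" %in% stages) {
    st$correlation <- mark_correlation(st$tag_densities)
    f <- file.path(out_dir, "mark_correlation.tsv")
    data.table::fwrite(data.frame(mark = rownames(st$correlation),
                                  st$correlation, check.names = FALSE),
                       f, sep = "\t", quote = FALSE)
    record(f, "correlate")
  }

  if ("ratio" %in% stages) {
    cls <- st$promoter_classes
    active <- cls$locus_id[cls$label == "active"]
    inactive <- cls$locus_id[cls$label == "inactive"]
    abort_if(length(active) == 0 || length(inactive) == 0,
             "ratio stage needs non-empty active and inactive classes")
    k14 <- st$tag_densities[, "H3K14ac"]
    k9 <- st$tag_densities[, "H3K9ac"]
    st$ratio <- ratio_statistic(k14, k9, active, inactive,
                                config$ratio_pseudocount)
    n_sel <- min(config$n_primed, length(inactive))
    st$primed <- select_primed_inactive(inactive, st$ratio, k14, n_sel)
    f <- file.path(out_dir, "primed_inactive.tsv")
    data.table::fwrite(data.frame(locus_id = st$primed,
                                  ratio = st$ratio$ratio[st$primed]),
                       f, sep = "\t", quote = FALSE)
    record(f, "ratio")
  }

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  st$manifest <- manifest
  invisible(as.list(st))
}

enhancer_loci_for <- function(config, st) {
  if (!is.null(config$enhancer_loci)) {
    x <- read_bed(config$enhancer_loci)
    return(reference_loci(
      ifelse(is.na(x$name), sprintf("enh_%d", seq_len(nrow(x))), x$name),
      x$chrom, floor((x$start + x$end) / 2), "."))
  }
  if (!is.null(st$genome)) return(st$genome$enhancers)
  NULL
}

#' Read a two-column chromosome sizes file
#' @param path tab-delimited `chrom <TAB> length`.
#' @return [chrom_sizes()].
#' @export
read_chrom_sizes <- function(path) {
  abort_if(is.null(path) || !file.exists(path),
           "chromosome sizes file not found: ", path %||% "<unset>")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  chrom_sizes(stats::setNames(as.numeric(dt[[2]]), as.character(dt[[1]])))
}

# Fail fast when a requested stage can get its inputs neither from the
# config nor from an earlier requested stage.
check_stage_inputs <- function(config, stages) {
  missing <- character(0)
  have_sim <- "simulate" %in% stages
  have_cov <- "coverage" %in% stages
  need_reads <- any(c("coverage", "correlate", "ratio") %in% stages)
  if (need_reads && !have_sim &&
      (is.null(config$reads) || is.null(config$input))) {
    missing <- c(missing, "reads/input BED files (or the simulate stage)")
  }
  if (any(stages != "simulate") && !have_sim &&
      (is.null(config$genes) || is.null(config$chrom_sizes))) {
    missing <- c(missing,
                 "gene table and chrom sizes (or the simulate stage)")
  }
  for (s in c("peaks", "profiles", "classify", "correlate", "ratio")) {
    if (s %in% stages && !have_cov) {
      missing <- c(missing, paste0("density tracks for stage '", s,
                                   "' (request the coverage stage)"))
    }
  }
  if ("annotate" %in% stages && !"peaks" %in% stages) {
    missing <- c(missing, "peak calls for stage 'annotate' (request the peaks stage)")
  }
  if ("ratio" %in% stages && !"classify" %in% stages) {
    missing <- c(missing, "promoter classes for stage 'ratio' (request the classify stage)")
  }
  abort_if(length(missing) > 0,
           "missing inputs for requested stages:\n  - ",
           paste(unique(missing), collapse = "\n  - "))
}
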
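---
title: "Models and methods behind chromstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic tests do and do not
demonstrate about real data.

# From reads to density tracks

Single-end ChIP-seq reads mark only the 5′ end of each
immunoprecipitated fragment.  `extend_reads()` therefore extends every
read to the theoretical fragment length (200 bp, the default used
throughout) in its own direction before any density computation; a `+`
read `[s, e)` becomes `[s, s+200)`, a `−` read `[e−200, e)`, clamped at
chromosome ends.  Reads with strand `"."` are treated as `+` with a
warning rather than aborting a run.

`bin_density()` tiles the genome with fixed-width bins (default 25 bp)
and stores, per bin, the **maximal per-base count of overlapping
extended reads** — max-overlap, not mean or sum.  A mean-valued profile
can always be produced downstream by resampling, but the track itself
keeps the max semantics; the test suite pins the implementation to a
brute-force per-base oracle on hundreds of random instances at bin
widths 1, 7 and 25.

All internal coordinates are 0-based half-open (the BED convention).
The single place any other convention appears is `write_wig()`, where
the WIG standard's 1-based positions require a `+1` shift; write→read
round trips are tested to be bit-identical so the shift cannot drift
into the rest of the code.

## Input normalization

The data's authors state only that signal was normalized to input DNA,
so the formula here is this package's choice, logged in results: with
per-million scaling `x_pm = x · 10⁶ / library`, each bin holds

    (chip_pm + p) / (control_pm + p),   p = 1 per-million unit.

Identical tracks normalize to exactly 1, and the value is invariant to
jointly rescaling both libraries.  At realistic sequencing depth the
per-bin control rate is well estimated; at the shallow depths of desk
scale simulations a single control read per 25 bp bin would swing the
ratio by an order of magnitude.  The pipeline therefore **smooths the
control track** (`smooth_track()`, centered rolling mean over 5 kb,
configurable via `control_smooth`) before taking the ratio — the same
reasoning behind local-lambda background models in peak callers: input
is expected to be locally flat, so its local mean estimates the
background rate far better than one bin's count.  The chip track is
never smoothed; profile shape comes from the numerator.

## The simplified peak caller

`call_peaks()` is a deliberately simple stand-in for a full
model-based caller, not a MACS clone.  Fixed 500 bp windows slide one
bin at a time; a window qualifies only if its summed chip signal
exceeds *both*

1. `mfold` (default 12) times the depth-scaled control expectation, and
2. a one-sided Poisson upper-tail test at `alpha` (default 1e-5)
   against the local control rate, floored by the genome-wide control
   rate.

Qualifying windows are merged when adjacent; each merged region reports
the left-most maximal bin as its summit (a deterministic tie-break) and
the fold/p-value of the best window covering the summit.  There is no
duplicate-read filtering, fragment-shift model, or dynamic band width;
how a platform-specific tag size would interact with the uniform 200 bp
extension is left out on purpose, and externally produced BED peak
lists can be substituted at any point downstream (`read_peaks()`).  On
input-vs-input null simulations the emitted-peak count stays within
`2·alpha·windows` (in practice near zero, because the mfold gate is far
stricter than the Poisson gate at background rates).  A weakly enriched
state (e.g. the 3-fold acetylation of bivalent promoters in the default
generator) falls below `mfold = 12` by design — the caller recovers
strong peaks, not every planted enrichment.

# Profiles

`collect_tss_matrix()` divides `[anchor − flank, anchor + flank)`
(default ±5 kb) into `n_bins` equal bins (default 100, i.e. 100 bp
bins) and fills each with the **base-weighted mean** of the track —
resampling a max-valued 25 bp track into wider profile bins by
averaging conserves totals, whereas max-of-max would compound the max
semantics.  Minus-strand rows are reversed so column 1 is always
5′-most; windows that run past a chromosome end are zero-filled on the
missing side and flagged rather than dropped, keeping matrix rows
aligned with locus lists for heatmaps.

`collect_gene_body_matrix()` maps every gene body onto 100
length-scaled bins flanked by fixed 50 bp bins.  The flank description
this follows is internally ambiguous — "10 equally sized (50 bp) bins"
covers 500 bp, while the profile axes span 5 kb — so the default tiles
the full 5 kb flank in 50 bp bins (100 per side); passing
`flank = 500` reproduces the literal 10-bin reading.  Genes shorter
than the bin count cannot be rescaled and are dropped with a count.

Composite profiles (`average_profile()`) are column means with
standard errors, computed on input-normalized bins *before* averaging
(normalize-then-average, matching "average input-normalized profile");
the alternative average-then-normalize reading can be had by averaging
raw matrices and normalizing the result by hand.

`stratify_by_expression()` ranks genes by descending expression into
contiguous near-equal groups (remainder to the top groups, ties broken
by gene id) and `sort_loci_by_score()` is a stable descending sort —
both deterministic by construction.

# Feature annotation

`build_partition()` assigns every base of the genome to exactly one of
promoter (2 kb upstream of the TSS, strand-oriented), coding exon,
intron, 2 kb downstream, or distal intergenic, resolving overlaps by
the precedence promoter > exon > intron > downstream > intergenic.
Two open readings were settled as follows and should be kept in mind
when comparing fractions with published numbers:

* "promoter" means the upstream 2 kb only; the first 2 kb downstream
  of the TSS belongs to the gene body;
* "coding exon" uses all annotated exons, because the minimal gene
  table carries no CDS boundaries.

`assign_peaks()` places each peak by **summit containment** (single
assignment, fractions sum to 1); an `any_overlap` mode reproduces the
multi-count reporting style of genome-annotation tools.
`intergenic_peaks()` keeps peaks whose total overlap with distal
intergenic intervals is ≥ 500 bp (boundary included), and is monotone
in the threshold.  `combine_tss_peak_sets()` takes the union of
promoters hit by either mark's peaks within a window of the TSS.

# Chromatin-state classification

`kmeans_cluster()` runs Lloyd's algorithm on per-mark `log(x+1)`
features standardized per mark, so a high-dynamic-range mark cannot
dominate the Euclidean distance.  The best of `n_restarts` (default
10) random starts by within-cluster sum of squares is kept; the run is
deterministic given the seed, and cluster ids are renumbered by
descending first-mark signal so reports are stable.  Duplicate-row
degenerate inputs short-circuit to the distinct rows with a warning.
`k = 3` is the default for promoters (three expected states) and
`k = 4` for enhancer heatmaps; labels never come from cluster indices
but from explicit rules on cluster summaries:

* a cluster is **marked** for a modification when its mean central
  density (±1 kb around the anchor for promoters) is at least
  `presence_factor` (default 2) times the genome-wide background;
* **bivalent** = marked(H3K4me3) ∧ marked(H3K27me3) — evaluated first;
* **active** = marked(H3K4me3) ∧ marked(Pol II) ∧ ¬marked(H3K27me3);
* **inactive** = everything else.

The published description never quantifies "presence", and the count
of genes "lacking" Pol II/H3K4me3 in the original analysis has no
stated threshold; the `presence_factor` rule is this package's
operationalization, carried in the outputs, and the test suite checks
that labels are insensitive to factors 1.5–3 when marks are well
separated.  The **background** fed to the rules by the pipeline is the
genome-wide median of the *smoothed* normalized track, i.e. the median
of the same windowed-mean statistic the rule thresholds; the median of
raw per-bin ratios sits lower in the skewed ratio distribution and, at
shallow depth, inside the noise tail of the per-locus statistic.

Enhancers are classified per locus: mean central H3K27ac (±500 bp)
at or above `presence_factor ×` background is *active*, otherwise
*poised*.  Because this is a per-locus threshold on a noisy statistic,
a small error rate near the threshold is inherent at desk-scale depth
(the poised statistic's upper tail crosses 2× background for roughly
2–3% of loci in the default generator); the planted split is recovered
at ≥ 95% accuracy, not always exactly.

`mark_correlation()` computes Pearson correlation of `log(x+1)` tag
densities (the scale of the published scatter plots is unstated; raw
scale is available via `log_transform = FALSE`); zero-variance marks
yield missing values, never 0.  `ratio_statistic()` forms
`(K14 + p)/(K9 + p)` on per-million densities (pseudocount 1), reports
group medians, and tests inactive > active with a one-sided
Wilcoxon rank-sum test.  `select_primed_inactive()` takes the top *n*
inactive promoters by ratio, ties broken by higher K14 density then
locus id.  The active/inactive gene sets default to the k-means-derived
promoter classes; an expression-based definition (top/bottom of the
expression ranking via `stratify_by_expression()`) is the supported
alternative.

# What the generator plants — and what it does not

`synthetic_spec()` describes a toy study: two 2 Mb chromosomes, 180
genes (60 active, 30 bivalent, 60 inactive, 30 primed) and 80 enhancers
(40 active, 40 poised) by default, placed in random slots ≥ 12 kb apart
so ±5 kb windows never collide.  Reads are 27 bases (typical early
short-read length) marking fragment ends, so the standard 200 bp
extension recovers the planted fragment positions.  Per state and mark,
enrichment reads are Poisson with amplitude `amp_base × fold` (defaults:
`amp_base` 30; active promoters fold 10/10/12/8 for
K9ac/K14ac/K4me3/Pol II; bivalent 3/3/8/8 for K9ac/K14ac/K4me3/K27me3;
primed 3 for K14ac only; active enhancers 8 for K4me1/K27ac plus 4 for
the acetylations; poised enhancers K4me1 only).  Promoter fragments
follow a two-component Gaussian mixture at TSS ± 200 bp (s.d. 150 bp)
with a 150 bp nucleosome-depleted region excluded by rejection
sampling — offsets are free parameters; published profiles report the
bimodal shape, not numbers.  The total-H3 track is uniform nucleosome
signal thinned (85%) inside active-promoter NDRs.  H3K9ac/H3K14ac
amplitudes share a latent log-normal factor with correlation `rho`
(default 0.7) and are multiplied by expression- and CpG-coupling
factors normalized within state, so a state's mean amplitude stays
`amp_base × fold` while within-state variation tracks expression and
CpG content.  Background is uniform Poisson (5 reads/kb per mark, and
for the input library).

The generator deliberately omits: sequence (reads are intervals, no
FASTA), mappability and GC bias, duplicate reads, copy-number
variation, unannotated transcription, overlapping genes, and broad
domain-type marks.  Passing tests therefore demonstrate the
*algorithms* — interval algebra, binning, normalization, clustering,
rule application, statistics — under the planted statistical structure;
they do not certify performance on real libraries, where background is
not uniform and states are not well separated.

## Scenario parameters used by the tests

Problem sizes were chosen so each check exercises the relevant
statistics comfortably:

* **state recovery**: 4 × 8 Mb chromosomes, 1,200 genes
  (400/200/400/200 across states), 300 enhancers, 7 marks — promoter
  and enhancer label accuracy ≥ 95% against the planted truth;
* **correlation recovery**: 5,000 single-state loci, couplings off,
  folds equal across the two marks, `rho ∈ {0, 0.5, 0.7, 0.9}` —
  measured log-density correlation within ±0.05 of the latent value
  (log amplitudes dominate the Poisson and background noise at these
  amplitudes, so attenuation is ~1%);
* **expression deciles**: 1,000 active genes with `expr_slope = 0.7`
  and `amp_sdlog = 0.4`.  At the default amplitude noise (0.8) strict
  decile ordering is not guaranteed — adjacent middle deciles differ by
  ~0.22 in log amplitude against a group-mean s.e. of ~0.08 — so the
  stratification scenario raises the coupling and lowers the noise
  until the adjacent-decile z-score is ~7, which makes the strict chain
  a property of the configuration rather than of a lucky seed;
* **primed contrast**: 200 active vs 200 inactive genes of which 120
  primed — rank-sum p < 0.01 and ≥ 90% recall of the planted primed
  set;
* **null calibration**: 20 independent input-vs-input simulations on
  2 Mb genomes.

# Degenerate inputs and tie-breaks

Empty read sets produce all-zero tracks; empty gene lists produce an
all-intergenic partition with a warning; genes shorter than the body
bin count are dropped with a count; anchors outside chromosome bounds
are errors; summit ties resolve left-most; sort ties preserve input
order; expression ties break by gene id; primed-selection ties break by
K14 density then id.  Every stochastic stage takes an explicit seed —
there is no silent clock seeding — and the pipeline manifest records
md5 hashes of all outputs so reruns can be compared bit for bit.

# Known limitations

* The peak caller is a calibrated simplification; peak boundaries are
  bin-quantized and weak enrichment below the mfold gate is invisible.
* Track-mode tag density sums max-valued bins and is documented as an
  approximation of the read count; reads-mode is exact.
* Per-locus enhancer presence calls carry an irreducible error rate
  near the threshold at low depth (see above).
* The genome partition treats all annotated exons as "coding" and
  resolves overlaps by a fixed precedence; fractions are not directly
  comparable to tools that multi-count or use CDS annotations.
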
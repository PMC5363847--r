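---
title: "Methods: windowed nucleosome-occupancy comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed nucleosome-occupancy comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucscan)
```

## The analysis

MNase-seq reports nucleosome positions: micrococcal nuclease digests linker
DNA, and the surviving ~147-bp fragments mark where histone octamers sat.
`nucscan` implements the comparative, window-level form of this analysis for
two cell populations. Every stage works on the same primitive: aligned
mononucleosome fragments (one BED3 record per sequenced read pair) counted
into fixed genomic windows and normalized as FPKM,

$$\mathrm{FPKM}_w = \frac{n_w}{(\ell_w/1000)\,(N/10^6)},$$

where $n_w$ is the fragment count of window $w$, $\ell_w$ its true length in
bp (trailing partial windows keep their real length), and $N$ the *library*
total. Because each library is scaled by its own $N$, tracks from libraries
of different depths are directly comparable and all downstream thresholds
are pure fold changes — no count model, no p-values. That is a deliberate
property of the method: differential windows are defined by
$\max(a,b)/\min(a,b) \ge$ a fold threshold, not by a significance test, and
the package documents it rather than quietly adding one.

The stages, each an exported function:

1. **Fragments** — `read_fragments()` / `pairs_to_fragments()` /
   `coverage_rate()`: ingest BED3 (or join read-pair tables), and measure the
   fraction of genome bases under at least one fragment.
2. **Occupancy** — `make_windows()`, `count_fragments()`, `fpkm()`:
   windowed FPKM tracks at two scales (10-kb bins for a coarse
   chromosome-level view, 500-bp windows for the differential scan).
3. **Differential** — `classify_bins()` at 1.5-fold on the coarse grid
   (categories increase/decrease/absent/other), `differential_windows()` at
   2-fold on the fine grid, `map_windows_to_genes()` for genic- and
   promoter-scope gene lists.
4. **Features** — `derive_feature_partition()` labels every base
   promoter/5'UTR/exon/intron/3'UTR/intergenic and
   `region_occupancy_ratio()` compares fragment shares to genome shares.
5. **Profiles** — `tss_metaprofile()` (±1 kb around the TSS in 10-bp bins,
   strand-aware), `profile_landmarks()` (NDR, +1, −1), and
   `gc_quintile_summary()` (FPKM distribution by GC-content quintile).
6. **Pipeline** — `run_compare()` orchestrates all of the above from file
   paths to a directory of tables plus a JSON manifest.

## Coordinate and counting conventions

All coordinates are 0-based half-open, the native convention of BED and
genePred; conversion to R's 1-based indexing happens only at sequence
access. Three conventions deserve explanation because the source analyses
they descend from leave them open:

**Fragment-to-window assignment.** Whether a boundary-spanning fragment
counts in one window or two is ambiguous. The default `midpoint` rule
assigns each fragment to the single window containing
$\lfloor(start+end)/2\rfloor$; it conserves total mass exactly
($\sum_w n_w = N$ when the grid covers the genome), which makes the
fold-change statistics well defined. The `overlap` rule (one count per
overlapped window) is available behind a flag; both are validated against a
brute-force per-(fragment, window) oracle in the tests.

**Feature precedence.** Transcripts overlap, and a base can be promoter of
one gene and intron of another. The partition resolves every base by fixed
precedence promoter > 5'UTR > 3'UTR > exon > intron > intergenic, so the
partition is an exact tiling (base counts sum to genome length — a property
test) and ratio tables sum to 100%. Promoter = 1000 bp immediately upstream
of the TSS by default, strand-aware and clipped at chromosome ends; the
value is configurable since no universal definition exists. Non-coding
transcripts contribute all exonic bases to `exon`. Record order never
matters (tested by permutation).

**Zero handling in fold changes.** A raw 2-fold rule calls a 1-vs-0 count
"differential", which is shot noise. `differential_windows()` therefore
pairs the fold threshold with a minimum-FPKM floor, by default the FPKM that
5 fragments produce in one window of the smaller library
(`default_min_fpkm()`). A window with one value 0 and the other above the
floor qualifies with fold ∞; both-zero windows are never selected. The
boundary is inclusive (exactly 2-fold qualifies) at both scales.

## TSS metaprofile geometry

Upstream must be left for both strands, and the two strands must be exactly
symmetric — not just approximately. The profile anchors at the
transcription-start *boundary* (`tx_start` on `+`, `tx_end` on `-`) and bins
the continuous fragment midpoint $(start+end)/2$; with this pairing,
mirroring every coordinate ($x \mapsto L - x$) and flipping strands leaves
the profile bit-identical, which the tests assert with `expect_identical()`.
(Anchoring at the TSS *base* instead introduces a 1-bp strand asymmetry for
even-length fragments.) Genes whose flank runs off a chromosome end are
clipped, and each bin is normalized by the number of genes actually covering
it, so truncated genes do not dilute edge bins — chosen because desk-scale
simulated chromosomes are short; on real genomes it changes little.

Landmarks are argmin/argmax over fixed search ranges (NDR: minimum in
[−300, 100); +1: maximum in [0, 300); −1: maximum in [−400, 0)), reported at
bin centers, ties broken toward the smaller offset. On a flat profile the
NDR lands on the first bin of its range — degenerate by construction and
documented rather than special-cased. The ranges are this package's own
choice (visual identification is the field's usual practice) and are
arguments.

## GC stratification

Each 500-bp window's GC fraction is computed from sequence with N bases
excluded from numerator and denominator; windows over 50% N are dropped.
Windows are ranked by GC (stable order, so equal-GC windows keep genomic
order) and cut into five equal-count groups (sizes differ by ≤ 1; with fewer
than five usable windows the empty groups are reported as such). Per group
and condition the FPKM five-number summary and mean are reported.

## The synthetic generator

`simulation_spec()` + `simulate_dataset()` generate complete studies with
known truth, replacing sequencing data none of the desk-scale analyses could
carry. What it emulates, with defaults and why:

| parameter | default | rationale |
|---|---|---|
| `spacing_mean` | 190 bp | 147-bp core + ~45-bp linker, the canonical repeat length |
| `fragment_length_mean/sd`, `length_bounds` | 147 / 10, [100, 200] bp | truncated-normal mononucleosome inserts |
| `ndr_halfwidth` | 70 bp | dyads within it of a TSS get weight 0 (the NDR) |
| `plus1_offset`, `minus1_offset` | +120 / −200 bp | phased +1/−1 dyads, transcription-direction signed |
| `phasing_weight` | 3 | −1/+1 dyads at 3× local background, so peaks are visible above background at moderate depth |
| `gc_block_length`, `gc_low/high` | 1 kb, 0.35–0.65 | isochore-like GC mosaic; block targets drawn uniformly in the range |
| `gc_coupling` | 1.0 | dyad weight ∝ 1 + coupling·(GC₁₄₇ − 0.5), clipped at 0 — positive GC–occupancy coupling |
| `depth` | 10⁵–3×10⁵ | desk scale; real studies run 10⁷–10⁸ read pairs |

Planted effects multiply dyad *weights* (not read counts) for one condition
inside a target interval or gene promoter, so the realized FPKM fold change
is subject to sampling noise and tests must use tolerances — deliberate,
because that is how a real biological effect behaves. Every stage seeds its
own RNG stream derived from `spec$seed`; identical specs give byte-identical
output files.

What the generator does **not** model: MNase sequence bias, mappability and
duplication artifacts, read-level errors (no FASTQ), chromatin heterogeneity
between cells, and non-nucleosomal protection. Passing the validation suite
therefore shows the *computational* pipeline is correct and calibrated under
clean sampling assumptions; it does not show robustness to those real-data
artifacts.

## Validation design and problem sizes

The validation suite runs at sizes chosen to keep the full test run within a
couple of minutes on one core while leaving comfortable statistical margins:

- **Counting correctness**: 100-kb genome, 10⁴ fragments, both rules and
  both widths against the brute-force oracle, exact.
- **Differential calibration**: 1-Mb genome, 20 genes, 3×10⁵ fragments per
  condition (~150 per 500-bp window). 60 window-aligned 3-fold effects are
  planted clear of TSSs (`select_planted_windows()`); at these depths a
  3-fold weight change is ~9 Poisson standard deviations from 1:1, so
  recovery should be near-total and the suite requires ≥ 90% with ≤ 1%
  false selections. The matching null run (nothing planted) must call
  ≤ 0.5% of windows: a 2-fold excursion at ~150 counts is a ~6σ event, so
  the expected rate is orders of magnitude below that ceiling.
- **Landmark recovery**: 50 genes, 2×10⁵ fragments; NDR center within the
  planted depleted span ± 20 bp, +1/−1 peaks within ± 20 bp (2 bins) of
  their planted offsets. Inside the NDR all bins are near zero, so the
  argmin's exact bin is tie-like; containment in the depleted span is the
  meaningful statement.
- **Strand symmetry within sampling tolerance**: the +-strand-only and
  −-strand-only profiles are *different genes* with different local GC
  backgrounds, so a pooled two-sample KS test with the iid null is
  miscalibrated at depth — gene-level heterogeneity inflates it without any
  strand asymmetry. The correct sampling unit is the gene: the suite uses a
  strand-label permutation test (200 permutations) of the pooled KS
  statistic, and the exact mirror test above remains the sharp check of
  strand handling.
- **GC monotonicity**: with coupling 1.0, quintile median FPKM must increase
  strictly in both conditions (adjacent quintile medians differ by ~6% of
  signal against a ~0.5% standard error of the median); with coupling 0 the
  Spearman ρ of the five medians must stay below 0.9 in absolute value.
- **Feature-ratio consistency**: 10⁵ uniform fragment midpoints over a
  hand-tiled single-gene partition; every label's fragment share must fall
  within 1.5 points of its genome share (the largest multinomial cell has a
  standard error of ~0.15 points).
- **Symmetries, exact**: condition swap relabels directions and categories;
  coordinate mirror + strand flip maps partitions and window counts
  one-to-one; annotation record permutation changes nothing.

`scripts/acceptance.R` recomputes these quantities from scratch at the same
sizes (about 15 s total) and writes them as JSON.

## Known limitations

- The per-base partition painter holds one integer per base per chromosome;
  fine for desk- and small-genome scale, memory-hungry beyond ~10⁸-bp
  chromosomes.
- BAM input is out of scope; convert name-sorted pairs to BED3 (or a pair
  table for `pairs_to_fragments()`) upstream. Alignment, duplicate marking
  and MAPQ filtering are assumed handled there.
- Coverage rate is defined as the per-base union fraction; window-level
  definitions would give different numbers.
- No GC-bias correction, no smoothing, and no nucleosome *calling* (dyad
  inference): the method operates at window resolution throughout, and
  scaled TSS→TES gene-body profiles are not implemented.
- GO enrichment is out of scope; the gene lists are written in a form that
  external tools accept.
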
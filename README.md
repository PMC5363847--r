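# nucscan

Comparative window-level nucleosome-occupancy analysis for paired MNase-seq
experiments, with a synthetic-data generator that plants known truth.

## The problem

MNase-seq maps nucleosomes: micrococcal nuclease digests exposed linker DNA
and the protected ~147-bp fragments report where histone octamers sat. To ask
how chromatin differs between two cell populations — e.g. growing vs fully
grown oocytes, where transcriptional activity changes sharply — the standard
window-level analysis is:

1. treat each aligned read pair as one fragment and tile the genome into
   fixed windows;
2. normalize per-window fragment counts as FPKM,
   `count / (window_kb × library_fragments/10⁶)`, so libraries of different
   depth are comparable;
3. classify 10-kb bins at a 1.5-fold threshold for a chromosome-scale view,
   and select 500-bp windows changing ≥ 2-fold for the differential scan
   (pure fold-change thresholds — this method family uses no count model or
   p-values);
4. relate occupancy to genomic context: per-feature fragment shares
   (promoter / 5'UTR / exon / intron / 3'UTR / intergenic) against genome
   shares, GC-content quintiles, and strand-aware ±1-kb TSS metaprofiles
   showing the −1 nucleosome, nucleosome-depleted region (NDR) and +1/+2
   array;
5. extract genes whose genic region or promoter carries differential
   windows, as input for downstream enrichment tools.

`nucscan` implements all of this as composable R functions plus a one-call
pipeline (`run_compare()`), and — because real oocyte-scale datasets run to
10⁸ read pairs — ships a generator (`simulation_spec()`,
`simulate_dataset()`) that builds complete synthetic studies: GC-mosaic
genomes, gene annotations, phased nucleosome maps with NDRs and GC-occupancy
coupling, and two-condition fragment sets with planted fold changes, so
every stage can be validated against ground truth.

## Worked example

The numbered scripts under `analysis/` run a complete synthetic study
(1-Mb genome, 20 genes, 3×10⁵ fragments per condition, 60 planted 3-fold
windows plus 3 planted promoter gains in condition "SF"):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_occupancy.R
Rscript analysis/03_differential.R
Rscript analysis/04_profiles.R
```

Step 3 prints:

```
500-bp windows with >= 2-fold change: 66 of 2000 (min FPKM 33.3)

up_in_SF
      66

planted-window recovery: 100.0% (60/60); false selections: 0
genes hit in genic scope: 6; in promoter scope: 3
planted promoter genes recovered: 3/3 (g0002, g0009, g0016)
```

i.e. every planted 3-fold window is recovered at the 2-fold threshold with
no false calls, and the three genes with planted promoter gains are exactly
the promoter-scope gene list. Step 4 prints the TSS landmarks,

```
 condition ndr_center plus1_peak minus1_peak
        BF        -55        125        -195
        SF        -55        125        -195
```

recovering the planted +1 (+120) and −1 (−200) dyads to within half a bin,
with the NDR minimum inside the planted depleted span (±70 bp), and shows
median FPKM rising monotonically across GC quintiles in both conditions —
the planted GC-occupancy coupling. Tables land under `results/`.

The same computations are available programmatically:

```r
library(nucscan)
genome <- read_genome_fasta("genome.fa")
ann    <- load_annotation("annotation.genePred", genome)
bf     <- read_fragments("fragments_BF.bed", genome)
sf     <- read_fragments("fragments_SF.bed", genome)

grid <- make_windows(genome, 500)
wins <- differential_windows(occupancy_track(bf, grid),
                             occupancy_track(sf, grid), fold = 2)
map_windows_to_genes(wins, ann, scope = "promoter")
```

or end-to-end via `run_compare(run_config(...))`, which writes every table
plus a JSON manifest.

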
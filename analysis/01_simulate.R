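#!/usr/bin/env Rscript
## Step 1: generate the synthetic two-condition MNase-seq study.
##
## One 1-Mb chromosome of 1-kb GC blocks, 20 genes, phased nucleosomes with
## an NDR and -1/+1 dyads at every TSS, GC-occupancy coupling 1.0, and two
## kinds of planted truth for condition "SF": 60 window-aligned 3-fold
## occupancy gains clear of any TSS, plus 3 gene promoters with a 3-fold
## gain. 3e5 fragments per condition (~44x fragment coverage).

source("analysis/00_config.R")

base <- simulation_spec(seed = SEED, chrom_length = CHROM_LENGTH,
                        n_genes = N_GENES, depth = DEPTH)
genome <- simulate_genome(base)
ann <- simulate_annotation(genome, base)
grid <- make_windows(genome, 500)

planted <- select_planted_windows(grid, ann, 60)
promoter_targets <- ann$gene_id[c(2, 9, 16)]
effects <- c(
  lapply(seq_len(nrow(planted)), function(i)
    list(chrom = planted$chrom[i], start = planted$start[i],
         end = planted$end[i], condition = "B", fold = 3.0)),
  lapply(promoter_targets, function(gid)
    list(gene = gid, condition = "B", fold = 3.0)))

spec <- simulation_spec(seed = SEED, chrom_length = CHROM_LENGTH,
                        n_genes = N_GENES, depth = DEPTH,
                        planted_effects = effects)
ds <- simulate_dataset(spec, DATA_DIR)

writeLines(promoter_targets, data_path("truth_promoter_genes.txt"))
cat(sprintf("simulated %d genes on a %.0f-kb genome; %d + %d planted effects\n",
            nrow(ann), CHROM_LENGTH / 1000, nrow(planted), length(promoter_targets)))
cat(sprintf("fragments per condition: %d (files under %s)\n", DEPTH, DATA_DIR))
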
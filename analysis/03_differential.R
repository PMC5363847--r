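#!/usr/bin/env Rscript
## Step 3: two-scale differential occupancy scan and gene extraction.
##
## 10-kb bins classified at 1.5-fold (coarse chromosome-scale view), then a
## 500-bp scan selecting >= 2-fold windows above the minimum-FPKM floor.
## Selected windows are checked against the planted truth and mapped to
## genes in genic and promoter scope.

source("analysis/00_config.R")

genome <- read_genome_fasta(data_path("genome.fa"))
ann <- load_annotation(data_path("annotation.genePred"), genome)
fsets <- lapply(CONDITIONS, function(cid)
  read_fragments(data_path(sprintf("fragments_%s.bed", cid)), genome))

## coarse view: 10-kb bins at 1.5-fold
grid10 <- make_windows(genome, 10000)
tr10 <- lapply(fsets, occupancy_track, grid = grid10)
bins <- classify_bins(tr10[[1]], tr10[[2]], fold = 1.5)
cat("10-kb bin categories (", names(CONDITIONS)[1], "vs", names(CONDITIONS)[2], "):\n")
print(table(bins$category))

## fine scan: 500-bp windows at 2-fold
grid <- make_windows(genome, 500)
tr <- lapply(fsets, occupancy_track, grid = grid)
wins <- differential_windows(tr[[1]], tr[[2]], fold = 2)
wins$direction <- ifelse(wins$direction == "up_in_a",
                         paste0("up_in_", names(CONDITIONS)[1]),
                         paste0("up_in_", names(CONDITIONS)[2]))
write.table(wins, res_path("differential_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n500-bp windows with >= 2-fold change: %d of %d (min FPKM %.1f)\n",
            nrow(wins), grid$total_windows, attr(wins, "min_fpkm")))
print(table(wins$direction))

## compare against planted truth
truth <- read.delim(data_path("truth_effects.bed"), header = FALSE,
                    col.names = c("chrom", "start", "end", "condition", "fold"))
tw <- truth[truth$end - truth$start == 500, ]         # window-aligned effects
key <- paste(wins$chrom, wins$start)
pkey <- paste(tw$chrom, tw$start)
up_sf <- key[wins$direction == paste0("up_in_", names(CONDITIONS)[2])]
## a selected window is a false call only if it overlaps no planted effect
## (the promoter effects span two windows each)
overlaps_truth <- vapply(seq_len(nrow(wins)), function(i)
  any(truth$chrom == wins$chrom[i] & truth$start < wins$end[i] &
        truth$end > wins$start[i]), logical(1))
cat(sprintf("\nplanted-window recovery: %.1f%% (%d/%d); false selections: %d\n",
            100 * mean(pkey %in% up_sf), sum(pkey %in% up_sf), nrow(tw),
            sum(!overlaps_truth)))

## gene extraction
genes_genic <- map_windows_to_genes(
  within(wins, direction <- ifelse(grepl(names(CONDITIONS)[1], direction),
                                   "up_in_a", "down_in_a")),
  ann, "genic", 1000)
genes_prom <- map_windows_to_genes(
  within(wins, direction <- ifelse(grepl(names(CONDITIONS)[1], direction),
                                   "up_in_a", "down_in_a")),
  ann, "promoter", 1000)
write_gene_list_tsv(genes_genic, res_path("genes_genic.tsv"))
write_gene_list_tsv(genes_prom, res_path("genes_promoter.tsv"))
planted_genes <- readLines(data_path("truth_promoter_genes.txt"))
cat(sprintf("genes hit in genic scope: %d; in promoter scope: %d\n",
            nrow(genes_genic), nrow(genes_prom)))
cat(sprintf("planted promoter genes recovered: %d/%d (%s)\n",
            sum(planted_genes %in% genes_prom$gene_id), length(planted_genes),
            paste(intersect(planted_genes, genes_prom$gene_id), collapse = ", ")))
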
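## Independent oracles and small fixture builders shared across tests.
## Oracles are deliberately naive (per-base vectors, double loops) so they
## share no code path with the implementation they check.

## brute-force per-(fragment, window) counting
oracle_window_counts <- function(fs, grid, rule = "midpoint") {
  tab <- window_table(grid)
  counts <- integer(nrow(tab))
  for (w in seq_len(nrow(tab))) {
    k <- fs$frags$chrom == tab$chrom[w]
    s <- fs$frags$start[k]; e <- fs$frags$end[k]
    if (rule == "midpoint") {
      mid <- (s + e) %/% 2
      counts[w] <- sum(mid >= tab$start[w] & mid < tab$end[w])
    } else {
      counts[w] <- sum(s < tab$end[w] & e > tab$start[w])
    }
  }
  counts
}

## per-base boolean coverage
oracle_coverage <- function(fs, genome) {
  covered <- 0
  for (chrom in genome$chroms) {
    hit <- logical(genome$lengths[[chrom]])
    k <- which(fs$frags$chrom == chrom)
    for (i in k) hit[(fs$frags$start[i] + 1):fs$frags$end[i]] <- TRUE
    covered <- covered + sum(hit)
  }
  covered / sum(genome$lengths)
}

## uniform random genome of given chromosome lengths
toy_genome <- function(lengths, seed = 1) {
  set.seed(seed)
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  genome_assembly(stats::setNames(Biostrings::DNAStringSet(seqs),
                                  names(lengths) %||% paste0("chr", seq_along(lengths))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frag_df <- function(chrom, start, end) data.frame(chrom = chrom, start = start, end = end)

## the worked single-gene 10-kb fixture: + gene, tx [2000,5000), cds
## [2500,4500), exons [2000,3000)+[4000,5000), promoter span 1000.
## Hand-tiled truth (independent interval arithmetic, frozen):
##   promoter [1000,2000)            1000 bp
##   utr5     [2000,2500)             500 bp
##   exon     [2500,3000)+[4000,4500) 1000 bp
##   intron   [3000,4000)            1000 bp
##   utr3     [4500,5000)             500 bp
##   intergenic [0,1000)+[5000,10000) 6000 bp
worked_annotation <- function() {
  gene_annotation(within_list_cols(data.frame(
    gene_id = "geneA", chrom = "chr1", strand = "+",
    tx_start = 2000L, tx_end = 5000L, cds_start = 2500L, cds_end = 4500L),
    exon_starts = list(c(2000L, 4000L)), exon_ends = list(c(3000L, 5000L))))
}

worked_truth_bases <- c(promoter = 1000, utr5 = 500, exon = 1000,
                        intron = 1000, utr3 = 500, intergenic = 6000)

within_list_cols <- function(df, ...) {
  cols <- list(...)
  for (nm in names(cols)) df[[nm]] <- I(cols[[nm]])
  df
}

## mirror all coordinates (x -> L - x) and flip strands of an annotation
mirror_annotation <- function(ann, lengths) {
  out <- ann
  for (i in seq_len(nrow(ann))) {
    L <- lengths[[ann$chrom[i]]]
    out$tx_start[i] <- L - ann$tx_end[i]
    out$tx_end[i] <- L - ann$tx_start[i]
    if (ann$cds_start[i] < ann$cds_end[i]) {
      out$cds_start[i] <- L - ann$cds_end[i]
      out$cds_end[i] <- L - ann$cds_start[i]
    } else {
      out$cds_start[i] <- out$cds_end[i] <- L - ann$cds_start[i]
    }
    out$exon_starts[[i]] <- rev(L - ann$exon_ends[[i]])
    out$exon_ends[[i]] <- rev(L - ann$exon_starts[[i]])
    out$strand[i] <- if (ann$strand[i] == "+") "-" else "+"
  }
  gene_annotation(as.data.frame(out)[, setdiff(names(out), "tss")])
}

mirror_fragments <- function(fs, lengths, chrom_order = NULL) {
  L <- lengths[fs$frags$chrom]
  fragment_set(frag_df(fs$frags$chrom, unname(L) - fs$frags$end,
                       unname(L) - fs$frags$start),
               chrom_order = chrom_order)
}

mirror_genome <- function(genome) {
  genome_assembly(Biostrings::reverse(genome$seqs))
}

## canonical interval form of a partition for comparisons
partition_key <- function(p) {
  d <- as.data.frame(p)[, c("chrom", "start", "end", "label")]
  d$label <- as.character(d$label)
  d <- d[order(d$chrom, d$start), ]
  rownames(d) <- NULL
  d
}
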
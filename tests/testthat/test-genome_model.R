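test_that("genePred parsing handles the documented cases", {
  f <- withr::local_tempfile()

  writeLines(character(), f)
  expect_equal(nrow(load_annotation(f)), 0)

  writeLines("geneA\tchr1\t+\t1000\t2000\t1200\t1800\t2\t1000,1500\t1300,2000", f)
  ann <- load_annotation(f)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$tss, 1000)
  expect_length(ann$exon_starts[[1]], 2)
  expect_equal(ann$exon_ends[[1]], c(1300L, 2000L))

  ## minus strand: TSS is the last covered base under half-open convention
  writeLines("geneB chr1 - 1000 2000 1000 2000 1 1000, 2000,", f)
  expect_equal(load_annotation(f)$tss, 1999)

  writeLines("geneC\tchr1\t+\t1000", f)
  expect_error(load_annotation(f), "line 1")

  writeLines(c("geneA\tchr1\t+\t1000\t2000\t1000\t2000\t1\t1000,\t2000,",
               "bad\tchr1\t+\t5000\t4000\t5000\t5000\t1\t5000,\t4000,"), f)
  expect_warning(ann <- load_annotation(f), "txStart >= txEnd")
  expect_equal(ann$gene_id, "geneA")

  writeLines("geneD\tchrZ\t+\t10\t50\t10\t50\t1\t10,\t50,", f)
  g <- toy_genome(c(chr1 = 1000))
  expect_warning(ann <- load_annotation(f, g), "absent from genome")
  expect_equal(nrow(ann), 0)
})

test_that("annotations round-trip through the genePred writer", {
  spec <- simulation_spec(seed = 11, chrom_length = 6e4, n_genes = 6, depth = 0)
  g <- simulate_genome(spec)
  ann <- simulate_annotation(g, spec)
  f <- withr::local_tempfile()
  write_annotation_genepred(ann, f)
  back <- load_annotation(f, g)
  expect_equal(back$gene_id, ann$gene_id)
  expect_equal(back$tx_start, ann$tx_start)
  expect_equal(back$tss, ann$tss)
  expect_equal(unclass(back$exon_starts), unclass(ann$exon_starts))
})

test_that("feature partition reproduces the hand-tiled single-gene layout", {
  g <- toy_genome(c(chr1 = 10000), seed = 3)
  p <- derive_feature_partition(worked_annotation(), g, promoter_span = 1000)
  w <- p$end - p$start
  bases <- vapply(names(worked_truth_bases),
                  function(lb) sum(w[p$label == lb]), numeric(1))
  expect_equal(bases, worked_truth_bases)
  expect_equal(sum(w), 10000)
  ## exact interval placement
  expect_equal(p$start[p$label == "promoter"], 1000)
  expect_equal(p$end[p$label == "utr3"], 5000)
  r <- compute_genome_ratios(p)
  expect_equal(r$percent[r$label == "intergenic"], 60)
  expect_equal(sum(r$percent), 100)
})

test_that("promoters are clipped at chromosome starts and edge genes survive", {
  g <- toy_genome(c(chr1 = 10000))
  ann <- gene_annotation(within_list_cols(data.frame(
    gene_id = "gE", chrom = "chr1", strand = "+",
    tx_start = 300L, tx_end = 1300L, cds_start = 300L, cds_end = 300L),
    exon_starts = list(300L), exon_ends = list(1300L)))
  p <- derive_feature_partition(ann, g, promoter_span = 1000)
  prom <- p[p$label == "promoter", ]
  expect_equal(c(prom$start, prom$end), c(0, 300))
  ## non-coding transcript: exonic bases are exon, no UTRs
  expect_equal(sum((p$end - p$start)[p$label == "exon"]), 1000)
  expect_equal(sum(p$label %in% c("utr5", "utr3")), 0)
})

test_that("gene-free chromosomes are fully intergenic and ratios are scale invariant", {
  g1 <- toy_genome(c(chr1 = 10000))
  empty <- gene_annotation(within_list_cols(data.frame(
    gene_id = character(), chrom = character(), strand = character(),
    tx_start = integer(), tx_end = integer(),
    cds_start = integer(), cds_end = integer()),
    exon_starts = list(), exon_ends = list()))
  p1 <- derive_feature_partition(empty, g1, 1000)
  expect_equal(nrow(p1), 1)
  expect_equal(as.character(p1$label), "intergenic")
  expect_equal(compute_genome_ratios(p1)$percent[6], 100)

  ## duplicating the chromosome (same gene on each copy) leaves ratios unchanged
  g2 <- genome_assembly(stats::setNames(
    Biostrings::DNAStringSet(c(as.character(g1$seqs[[1]]), as.character(g1$seqs[[1]]))),
    c("chr1", "chr2")))
  ann1 <- worked_annotation()
  ann2 <- ann1[c(1, 1), ]; ann2$chrom <- c("chr1", "chr2"); ann2$gene_id <- c("a", "b")
  ann2 <- gene_annotation(as.data.frame(ann2)[, setdiff(names(ann2), "tss")])
  r1 <- compute_genome_ratios(derive_feature_partition(ann1, g1, 1000))
  r2 <- compute_genome_ratios(derive_feature_partition(ann2, g2, 1000))
  expect_equal(r1$percent, r2$percent)
})

test_that("partition conserves base counts and ignores record order", {
  for (seed in c(5, 6)) {
    spec <- simulation_spec(seed = seed, chrom_length = 5e4, n_chrom = 2,
                            n_genes = 8, depth = 0)
    g <- simulate_genome(spec)
    ann <- simulate_annotation(g, spec)
    p <- derive_feature_partition(ann, g, 700)
    expect_equal(sum(p$end - p$start), sum(g$lengths))
    set.seed(seed)
    perm <- ann[sample(nrow(ann)), ]
    perm <- gene_annotation(as.data.frame(perm)[, setdiff(names(perm), "tss")])
    expect_identical(partition_key(derive_feature_partition(perm, g, 700)),
                     partition_key(p))
  }
})

test_that("mirroring coordinates and flipping strands mirrors the partition", {
  spec <- simulation_spec(seed = 9, chrom_length = 4e4, n_genes = 5, depth = 0)
  g <- simulate_genome(spec)
  ann <- simulate_annotation(g, spec)
  p <- derive_feature_partition(ann, g, 800)
  pm <- derive_feature_partition(mirror_annotation(ann, g$lengths),
                                 mirror_genome(g), 800)
  L <- g$lengths[["chr1"]]
  back <- data.frame(chrom = pm$chrom, start = L - pm$end, end = L - pm$start,
                     label = as.character(pm$label))
  expect_identical(partition_key(back), partition_key(p))
})
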
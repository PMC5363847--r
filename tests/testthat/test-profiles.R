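single_gene_ann <- function(strand = "+", tx_start = 5000L, tx_end = 8000L) {
  gene_annotation(within_list_cols(data.frame(
    gene_id = "g1", chrom = "chr1", strand = strand,
    tx_start = tx_start, tx_end = tx_end,
    cds_start = tx_start, cds_end = tx_end),
    exon_starts = list(tx_start), exon_ends = list(tx_end)))
}

test_that("TSS metaprofile bins midpoints on a strand-aware axis", {
  g <- toy_genome(c(chr1 = 20000), seed = 61)
  ann <- single_gene_ann()          # + strand, TSS boundary at 5000

  empty <- fragment_set(frag_df(character(), integer(), integer()))
  p0 <- tss_metaprofile(empty, ann, g)
  expect_true(all(p0$value == 0))
  expect_equal(length(p0$value), 200)

  ## one fragment with midpoint at TSS+5 -> only the [0,10) bin is nonzero
  fs <- fragment_set(frag_df("chr1", 4932, 5078))   # center 5005
  p <- tss_metaprofile(fs, ann, g)
  expect_equal(which(p$counts > 0), 101)
  expect_equal(p$offset[101], 5)
  ## value = count / (bin_kb * total/1e6 * n_genes)
  expect_equal(p$value[101], 1 / (0.01 * 1e-6 * 1), tolerance = 1e-9)

  expect_error(tss_metaprofile(fs, ann[0, ], g), "empty annotation")
  expect_error(tss_metaprofile(fs, ann, g, flank = 1000, bin = 7), "divisible")
})

test_that("profile mass equals midpoints inside flanks, with multiplicity", {
  spec <- simulation_spec(seed = 62, chrom_length = 8e4, n_genes = 6, depth = 8000)
  g <- simulate_genome(spec)
  ann <- simulate_annotation(g, spec)
  map <- plant_nucleosome_map(g, ann, spec)
  fs <- simulate_fragments(map, "A", 8000, spec)
  p <- tss_metaprofile(fs, ann, g)
  mids <- (fs$frags$start + fs$frags$end) / 2
  expected <- 0
  for (i in seq_len(nrow(ann))) {
    a <- if (ann$strand[i] == "+") ann$tx_start[i] else ann$tx_end[i]
    expected <- expected + if (ann$strand[i] == "+")
      sum(mids >= a - 1000 & mids < a + 1000)
    else sum(mids > a - 1000 & mids <= a + 1000)
  }
  expect_equal(sum(p$counts), expected)
})

test_that("mirroring the dataset leaves the metaprofile unchanged", {
  spec <- simulation_spec(seed = 63, chrom_length = 6e4, n_genes = 5, depth = 5000)
  g <- simulate_genome(spec)
  ann <- simulate_annotation(g, spec)
  map <- plant_nucleosome_map(g, ann, spec)
  fs <- simulate_fragments(map, "A", 5000, spec)
  p <- tss_metaprofile(fs, ann, g)
  gm <- mirror_genome(g)
  pm <- tss_metaprofile(mirror_fragments(fs, g$lengths, gm$chroms),
                        mirror_annotation(ann, g$lengths), gm)
  expect_identical(p$counts, pm$counts)
  expect_identical(p$n_genes_bin, pm$n_genes_bin)
  expect_equal(p$value, pm$value)
})

test_that("landmark search uses bin centers with ties toward smaller offsets", {
  mk_profile <- function(value) {
    nb <- length(value)
    structure(list(offset = -1000 + (seq_len(nb) - 0.5) * (2000 / nb),
                   value = value, counts = value, n_genes_bin = rep(1L, nb),
                   n_genes = 1L, flank = 1000L, bin = as.integer(2000 / nb),
                   total_fragments = 1L), class = "TssProfile")
  }
  v <- rep(1, 200)
  v[96] <- 0                       # offset -45
  v[115] <- 5; v[130] <- 5         # tie at +145 / +295: smaller offset wins
  v[55] <- 4; v[75] <- 4           # tie at -455 (outside range) / -255
  lm <- profile_landmarks(mk_profile(v))
  expect_equal(lm$ndr_center, -45)
  expect_equal(lm$plus1_peak, 145)
  expect_equal(lm$minus1_peak, -255)

  ## flat nonzero profile: documented degenerate case, first bin of the range
  flat <- profile_landmarks(mk_profile(rep(1, 200)))
  expect_equal(flat$ndr_center, -295)
  expect_equal(flat$plus1_peak, 5)

  expect_error(profile_landmarks(mk_profile(rep(0, 200))), "all-zero")
})

test_that("GC quintiles have equal counts and summarize per condition", {
  g <- toy_genome(c(chr1 = 5000), seed = 64)
  grid <- make_windows(g, 500)     # 10 windows -> quintiles of exactly 2
  tr <- fpkm(rep(10L, 10), grid, 1e5)
  s <- gc_quintile_summary(list(A = tr, B = tr), g)
  expect_equal(unique(s$n_windows), 2)
  expect_equal(nrow(s), 10)
  expect_true(all(diff(s$gc_min[s$condition == "A"]) >= 0))

  ## equal-count property holds when window counts don't divide by 5
  g2 <- toy_genome(c(chr1 = 6300), seed = 65)
  s2 <- gc_quintile_summary(list(A = fpkm(rep(1L, 13), make_windows(g2, 500), 100)), g2)
  expect_lte(diff(range(s2$n_windows)), 1)
  expect_equal(sum(s2$n_windows), 13)

  ## degenerate: identical GC everywhere still yields equal-count groups
  gflat <- genome_assembly(c(chr1 = paste(rep("ACGT", 1250), collapse = "")))
  s3 <- gc_quintile_summary(list(A = fpkm(rep(1L, 10), make_windows(gflat, 500), 100)), gflat)
  expect_equal(unique(s3$n_windows), 2)
})

test_that("N-rich windows are excluded from GC stratification", {
  seqs <- paste0(paste(rep("N", 800), collapse = ""),
                 paste(rep("ACGT", 550), collapse = ""))
  g <- genome_assembly(c(chr1 = seqs))
  grid <- make_windows(g, 500)     # first window all-N, second 60% N
  tr <- fpkm(rep(1L, grid$total_windows), grid, 100)
  s <- gc_quintile_summary(list(A = tr), g)
  expect_equal(sum(s$n_windows[!duplicated(s$quintile)]), grid$total_windows - 2)
})
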
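test_that("the generator is deterministic end-to-end", {
  spec <- simulation_spec(seed = 21, chrom_length = 3e4, n_genes = 3, depth = 2000)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_dataset(spec, d1)
  r2 <- simulate_dataset(spec, d2)
  for (f in c("genome", "annotation", "dyads", "effects", "fragments_A", "fragments_B")) {
    expect_identical(readLines(r1[[f]]), readLines(r2[[f]]), label = f)
  }
})

test_that("genome blocks realize their GC targets", {
  spec <- simulation_spec(seed = 22, chrom_length = 5e4, gc_block_length = 1000,
                          gc_low = 0.5, gc_high = 0.5, n_genes = 0, depth = 0)
  g <- simulate_genome(spec)
  gc <- interval_gc(g, "chr1", seq(0, 49000, 1000), seq(1000, 50000, 1000))$gc
  ## binomial at n=1000, p=0.5: essentially all blocks within +/- 0.05
  expect_true(all(abs(gc - 0.5) < 0.05))

  at_only <- simulate_genome(simulation_spec(seed = 23, chrom_length = 2000,
                                             gc_low = 0, gc_high = 0,
                                             n_genes = 0, depth = 0))
  expect_false(grepl("[GC]", as.character(at_only$seqs[[1]])))
})

test_that("simulated annotations are valid and respect gene spacing", {
  spec <- simulation_spec(seed = 24, chrom_length = 1e5, n_genes = 12, depth = 0,
                          promoter_span = 1000)
  g <- simulate_genome(spec)
  ann <- simulate_annotation(g, spec)   # gene_annotation() enforces invariants
  expect_equal(nrow(ann), 12)
  o <- order(ann$tx_start)
  gaps <- ann$tx_start[o][-1] - ann$tx_end[o][-nrow(ann)]
  expect_true(all(gaps >= 2 * spec$promoter_span))

  expect_equal(nrow(simulate_annotation(g, simulation_spec(seed = 24,
    chrom_length = 1e5, n_genes = 0, depth = 0))), 0)

  ## too-small genome: fewer genes with a warning
  tiny <- simulation_spec(seed = 25, chrom_length = 12000, n_genes = 50, depth = 0)
  expect_warning(a2 <- simulate_annotation(simulate_genome(tiny), tiny),
                 "too small")
  expect_lt(nrow(a2), 50)
})

test_that("planted map obeys NDR, GC-coupling and fold rules", {
  spec <- simulation_spec(seed = 26, chrom_length = 6e4, n_genes = 4,
                          gc_coupling = 0, depth = 0,
                          planted_effects = list(
                            list(chrom = "chr1", start = 30000, end = 31000,
                                 condition = "B", fold = 3)))
  g <- simulate_genome(spec)
  ann <- simulate_annotation(g, spec)
  map <- plant_nucleosome_map(g, ann, spec)

  ## NDR: every dyad within the halfwidth of a TSS has zero weight
  for (t in ann$tss) {
    near <- abs(map$dyads$pos - t) <= spec$ndr_halfwidth
    expect_true(all(map$weights[near, ] == 0))
  }
  ## gc_coupling = 0: background weights all equal, phased dyads elevated
  w <- map$weights[, "A"]
  pos_w <- w[w > 0]
  expect_setequal(unique(pos_w), c(1, spec$phasing_weight))
  ## planted 3-fold: B/A ratio over positive dyads in the interval is exactly 3
  k <- map$dyads$pos >= 30000 & map$dyads$pos < 31000 & map$weights[, "A"] > 0
  expect_true(any(k))
  expect_equal(map$weights[k, "B"] / map$weights[k, "A"], rep(3, sum(k)))
  ## and outside it the conditions are identical
  expect_equal(map$weights[!k, "B"], map$weights[!k, "A"])

  ## gene-free, coupling-free map is perfectly uniform
  spec0 <- simulation_spec(seed = 26, chrom_length = 6e4, n_genes = 0,
                           gc_coupling = 0, depth = 0)
  ann0 <- simulate_annotation(g, spec0)
  map0 <- plant_nucleosome_map(g, ann0, spec0)
  expect_equal(unique(as.vector(map0$weights)), 1)
})

test_that("fragment sampling matches its length and weight model", {
  spec <- simulation_spec(seed = 27, chrom_length = 5e4, n_genes = 0,
                          gc_coupling = 0, depth = 10000)
  g <- simulate_genome(spec)
  map <- plant_nucleosome_map(g, simulate_annotation(g, simulation_spec(
    seed = 27, chrom_length = 5e4, n_genes = 0, depth = 0)), spec)

  expect_equal(simulate_fragments(map, "A", 0, spec)$total_fragments, 0)

  fs <- simulate_fragments(map, "A", 10000, spec)
  expect_equal(fs$total_fragments, 10000)
  len <- fs$frags$end - fs$frags$start
  expect_true(all(len >= 100 & len <= 200))
  ## CLT bound: sd 10, n 1e4 -> mean within 147 +/- 1
  expect_lt(abs(mean(len) - 147), 1)

  ## two dyads with weights 1 and 3: counts within 3 binomial sd of 1:3
  map2 <- structure(list(
    dyads = data.frame(chrom = "chr1", pos = c(10000L, 30000L)),
    weights = matrix(c(1, 3), ncol = 1, dimnames = list(NULL, "A")),
    conditions = "A", chrom_lengths = c(chr1 = 50000L), effects = list()),
    class = "NucleosomeMap")
  fs2 <- simulate_fragments(map2, "A", 40000, spec)
  n_first <- sum(fs2$frags$start < 20000)
  expect_lt(abs(n_first - 10000), 3 * sqrt(40000 * 0.25 * 0.75))

  expect_error(simulate_fragments(map2, "Z", 10, spec), "unknown condition")
  map2$weights[, 1] <- 0
  expect_error(simulate_fragments(map2, "A", 10, spec), "no nucleosome signal")
})

test_that("with zero jitter and fixed length, fragment midpoints sit on dyads", {
  spec <- simulation_spec(seed = 28, chrom_length = 4e4, n_genes = 0,
                          dyad_jitter_sd = 0, fragment_length_sd = 0,
                          gc_coupling = 0, depth = 3000)
  g <- simulate_genome(spec)
  ann <- simulate_annotation(g, spec)
  map <- plant_nucleosome_map(g, ann, spec)
  fs <- simulate_fragments(map, "A", 3000, spec)
  len <- fs$frags$end - fs$frags$start
  mids <- (fs$frags$start + fs$frags$end) %/% 2
  ## fragments clipped at chromosome ends lose the dyad-centering, so the
  ## exact identity holds for the full-length (unclipped) ones
  expect_gt(mean(len == 147), 0.98)
  expect_true(all(mids[len == 147] %in% map$dyads$pos))
})
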
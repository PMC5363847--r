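#' Specification for a synthetic two-condition MNase-seq dataset
#'
#' Captures every knob of the generator: genome composition (GC blocks),
#' gene placement, nucleosome phasing around the TSS (-1 / NDR / +1), the
#' GC-occupancy coupling, fragment-length model and sequencing depth, plus a
#' list of condition-specific planted fold changes that give downstream
#' stages a known truth.
#'
#' @param seed integer RNG seed; every generator stage derives its stream
#'   from it, so identical specs give byte-identical outputs.
#' @param n_chrom,chrom_length number and length (bp) of chromosomes.
#' @param gc_block_length bp; the genome is a mosaic of blocks whose GC
#'   target is drawn uniformly in `[gc_low, gc_high]`.
#' @param gc_low,gc_high GC fraction bounds of the blocks.
#' @param n_genes transcripts to place (non-overlapping, both strands).
#' @param tx_length_range transcript length range in bp.
#' @param spacing_mean bp between background dyads (147-bp core + linker;
#'   default 190).
#' @param dyad_jitter_sd sd (bp) of dyad placement and of per-fragment
#'   positional jitter.
#' @param ndr_halfwidth bp; dyads within this distance of a TSS get weight 0.
#' @param plus1_offset,minus1_offset signed bp offsets (transcription
#'   direction) of the phased +1 / -1 dyads from the TSS.
#' @param phasing_weight weight multiplier of the phased -1/+1 dyads over the
#'   local background.
#' @param gc_coupling weight multiplier slope: base weight is
#'   `1 + gc_coupling * (local GC - 0.5)`, clipped at 0.
#' @param fragment_length_mean,fragment_length_sd,length_bounds truncated
#'   normal fragment-length model (defaults 147 / 10 / \[100, 200\]).
#' @param depth fragments to draw per condition.
#' @param promoter_span bp; used for inter-gene spacing and promoter-targeted
#'   planted effects.
#' @param conditions condition identifiers (default `c("A", "B")`).
#' @param planted_effects list of effects, each
#'   `list(chrom=, start=, end=, condition=, fold=)` or
#'   `list(gene=, condition=, fold=)` (the gene form targets its promoter).
#' @return `SimulationSpec`.
#' @export
simulation_spec <- function(seed = 1L, n_chrom = 1L, chrom_length = 1e6,
                            gc_block_length = 1000L, gc_low = 0.35, gc_high = 0.65,
                            n_genes = 20L, tx_length_range = c(2000L, 4000L),
                            spacing_mean = 190L, dyad_jitter_sd = 5,
                            ndr_halfwidth = 70L, plus1_offset = 120L,
                            minus1_offset = -200L, phasing_weight = 3,
                            gc_coupling = 1.0,
                            fragment_length_mean = 147, fragment_length_sd = 10,
                            length_bounds = c(100L, 200L), depth = 1e5,
                            promoter_span = 1000L,
                            conditions = c("A", "B"), planted_effects = list()) {
  stopifnot(n_chrom >= 1, chrom_length > 0, gc_block_length > 0,
            gc_low >= 0, gc_high <= 1, gc_low <= gc_high,
            n_genes >= 0, spacing_mean > 0, dyad_jitter_sd >= 0,
            ndr_halfwidth > 0, phasing_weight > 0,
            fragment_length_mean > 0, fragment_length_sd >= 0,
            length_bounds[1] > 0, length_bounds[1] <= length_bounds[2],
            depth >= 0, promoter_span > 0, length(conditions) >= 1)
  for (eff in planted_effects) {
    if (is.null(eff$fold) || eff$fold <= 0) stopf("planted effect fold must be > 0")
    if (!(eff$condition %in% conditions)) stopf("planted effect names unknown condition")
    if (is.null(eff$gene) && (is.null(eff$chrom) || is.null(eff$start) || is.null(eff$end))) {
      stopf("planted effect needs either gene= or chrom=/start=/end=")
    }
  }
  spec <- as.list(environment())
  for (nm in c("seed", "n_chrom", "chrom_length", "gc_block_length", "n_genes",
               "tx_length_range", "spacing_mean", "ndr_halfwidth",
               "plus1_offset", "minus1_offset", "length_bounds",
               "promoter_span")) {
    spec[[nm]] <- as.integer(spec[[nm]])
  }
  structure(spec, class = "SimulationSpec")
}

## per-stage seed offsets keep generator streams independent but derived
## from one user-facing seed (all well below 2^31)
.stage_seed <- function(spec, stage) {
  spec$seed + c(genome = 101L, annotation = 202L, map = 303L,
                fragments = 404L)[[stage]]
}

#' Simulate a genome as a mosaic of GC blocks
#'
#' Each `gc_block_length` block draws a GC target uniformly in
#' `[gc_low, gc_high]` and bases are sampled i.i.d. at that composition,
#' giving the block-scale GC heterogeneity that the quintile stratification
#' analyses rely on. Deterministic given `spec$seed`.
#'
#' @param spec `SimulationSpec`.
#' @return `GenomeAssembly` with chromosomes `chr1..chrN`.
#' @export
simulate_genome <- function(spec) {
  set.seed(.stage_seed(spec, "genome"))
  L <- as.integer(spec$chrom_length)
  B <- as.integer(spec$gc_block_length)
  seqs <- vapply(seq_len(spec$n_chrom), function(ci) {
    nb <- ceiling(L / B)
    gtar <- if (spec$gc_low == spec$gc_high) rep(spec$gc_low, nb)
            else stats::runif(nb, spec$gc_low, spec$gc_high)
    per_base_gc <- rep(gtar, each = B)[seq_len(L)]
    is_gc <- stats::runif(L) < per_base_gc
    pick <- stats::runif(L) < 0.5
    base <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
    paste(base, collapse = "")
  }, character(1))
  genome_assembly(stats::setNames(Biostrings::DNAStringSet(seqs),
                                  paste0("chr", seq_len(spec$n_chrom))))
}

#' Simulate a gene annotation
#'
#' Places up to `n_genes` non-overlapping transcripts (random strand, 1-3
#' exons, ~90% coding with CDS bounds inside the terminal exons) with at
#' least `2 * promoter_span` bp between transcripts. If the genome cannot
#' hold the requested count, fewer genes are generated with a warning.
#'
#' @param genome `GenomeAssembly`.
#' @param spec `SimulationSpec`.
#' @return `GeneAnnotation`.
#' @export
simulate_annotation <- function(genome, spec) {
  set.seed(.stage_seed(spec, "annotation"))
  gap <- 2L * spec$promoter_span
  recs <- list()
  remaining <- spec$n_genes
  for (chrom in genome$chroms) {
    if (remaining <= 0) break
    L <- genome$lengths[[chrom]]
    pos <- gap
    while (remaining > 0) {
      txlen <- sample(spec$tx_length_range[1]:spec$tx_length_range[2], 1)
      start <- pos + sample(0:500, 1)
      if (start + txlen + gap > L) break
      txend <- start + txlen
      strand <- sample(c("+", "-"), 1)
      k <- sample(1:3, 1)
      if (k == 1) {
        es <- start; ee <- txend
      } else {
        ## 2*(k-1) interior cut points on a 50-bp lattice, keeping every
        ## exon/intron at least ~150 bp
        lat <- seq(start + 200L, txend - 200L, by = 50L)
        cuts <- sort(sample(lat, 2 * (k - 1)))
        while (any(diff(cuts) < 150L)) cuts <- sort(sample(lat, 2 * (k - 1)))
        es <- c(start, cuts[seq(2, length(cuts), by = 2)])
        ee <- c(cuts[seq(1, length(cuts), by = 2)], txend)
      }
      first_len <- ee[1] - es[1]; last_len <- ee[k] - es[k]
      coding <- stats::runif(1) < 0.9 && first_len > 100 && last_len > 100
      if (coding) {
        cs <- es[1] + sample(50:(first_len - 50), 1)
        ce <- ee[k] - sample(50:(last_len - 50), 1)
        if (cs >= ce) coding <- FALSE
      }
      if (!coding) { cs <- start; ce <- start }
      recs[[length(recs) + 1L]] <- list(
        gene_id = sprintf("g%04d", length(recs) + 1L), chrom = chrom,
        strand = strand, tx_start = start, tx_end = txend,
        cds_start = cs, cds_end = ce, exon_starts = es, exon_ends = ee)
      pos <- txend + gap
      remaining <- remaining - 1L
    }
  }
  if (remaining > 0 && spec$n_genes > 0) {
    warnf("genome too small for %d genes; generated %d",
          spec$n_genes, spec$n_genes - remaining)
  }
  df <- data.frame(
    gene_id = vapply(recs, `[[`, character(1), "gene_id"),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    tx_start = vapply(recs, `[[`, integer(1), "tx_start"),
    tx_end = vapply(recs, `[[`, integer(1), "tx_end"),
    cds_start = vapply(recs, `[[`, integer(1), "cds_start"),
    cds_end = vapply(recs, `[[`, integer(1), "cds_end"))
  df$exon_starts <- I(lapply(recs, `[[`, "exon_starts"))
  df$exon_ends <- I(lapply(recs, `[[`, "exon_ends"))
  gene_annotation(df)
}

## strand-aware promoter interval of one annotation record
.promoter_interval <- function(rec, span, L) {
  if (rec$strand == "+") c(max(0L, rec$tx_start - span), rec$tx_start)
  else c(rec$tx_end, min(L, rec$tx_end + span))
}

#' Plant the ground-truth nucleosome map
#'
#' Background dyads sit every `spacing_mean` bp with Gaussian jitter; each
#' dyad's base weight is `1 + gc_coupling * (GC_147bp - 0.5)` (clipped at 0),
#' coupling occupancy positively to local GC. Dyads within `ndr_halfwidth`
#' of any TSS are zeroed (the NDR); strand-aware -1/+1 dyads are added at
#' `minus1_offset`/`plus1_offset` from each TSS with `phasing_weight` times
#' the local background weight. All conditions share this base weight;
#' planted effects then multiply the weights of dyads inside their target
#' interval for their condition only.
#'
#' @param genome `GenomeAssembly`.
#' @param ann `GeneAnnotation`.
#' @param spec `SimulationSpec`.
#' @return `NucleosomeMap`: list with `dyads` (data frame `chrom`, `pos`),
#'   `weights` (matrix, one column per condition), `conditions`,
#'   `chrom_lengths`, and `effects` (resolved planted-effect intervals).
#' @export
plant_nucleosome_map <- function(genome, ann, spec) {
  set.seed(.stage_seed(spec, "map"))
  chroms <- character(); poss <- integer(); wts <- numeric()
  half <- 73L   # 147-bp local GC window
  for (chrom in genome$chroms) {
    L <- genome$lengths[[chrom]]
    pos <- as.integer(round(seq(spec$spacing_mean / 2, L - 1, by = spec$spacing_mean)))
    if (spec$dyad_jitter_sd > 0) {
      pos <- pos + as.integer(round(stats::rnorm(length(pos), 0, spec$dyad_jitter_sd)))
    }
    pos <- pmin(pmax(pos, 0L), L - 1L)
    tss <- ann$tss[ann$chrom == chrom]
    strand <- ann$strand[ann$chrom == chrom]
    ## phased dyads (before weight computation so GC weighting is uniform)
    ph_pos <- integer(); ph_w <- numeric()
    if (length(tss)) {
      sgn <- ifelse(strand == "+", 1L, -1L)
      ph_pos <- c(tss + sgn * spec$minus1_offset, tss + sgn * spec$plus1_offset)
      ph_pos <- pmin(pmax(as.integer(ph_pos), 0L), L - 1L)
      ph_w <- rep(spec$phasing_weight, length(ph_pos))
    }
    all_pos <- c(pos, ph_pos)
    mult <- c(rep(1, length(pos)), ph_w)
    gc <- interval_gc(genome, chrom, pmax(0L, all_pos - half),
                      pmin(L, all_pos + half + 1L))$gc
    gc[is.na(gc)] <- 0.5
    w <- pmax(0, 1 + spec$gc_coupling * (gc - 0.5)) * mult
    if (length(tss)) {
      for (t in tss) {
        ndr <- abs(all_pos - t) <= spec$ndr_halfwidth
        w[ndr] <- 0
      }
    }
    o <- order(all_pos)
    chroms <- c(chroms, rep(chrom, length(all_pos)))
    poss <- c(poss, all_pos[o]); wts <- c(wts, w[o])
  }
  weights <- matrix(rep(wts, length(spec$conditions)), ncol = length(spec$conditions),
                    dimnames = list(NULL, spec$conditions))
  ## resolve and apply planted effects
  effects <- list()
  for (eff in spec$planted_effects) {
    if (!is.null(eff$gene)) {
      i <- match(eff$gene, ann$gene_id)
      if (is.na(i)) stopf("planted effect targets unknown gene %s", eff$gene)
      iv <- .promoter_interval(ann[i, ], spec$promoter_span,
                               genome$lengths[[ann$chrom[i]]])
      eff$chrom <- ann$chrom[i]; eff$start <- iv[1]; eff$end <- iv[2]
    }
    k <- chroms == eff$chrom & poss >= eff$start & poss < eff$end
    weights[k, eff$condition] <- weights[k, eff$condition] * eff$fold
    effects[[length(effects) + 1L]] <- eff
  }
  structure(list(dyads = data.frame(chrom = chroms, pos = poss),
                 weights = weights, conditions = spec$conditions,
                 chrom_lengths = genome$lengths, effects = effects),
            class = "NucleosomeMap")
}

#' Draw sequenced fragments from a nucleosome map
#'
#' Each fragment picks a dyad with probability proportional to its weight for
#' the chosen condition, jitters the dyad position by
#' `Normal(0, dyad_jitter_sd)`, draws a length from the truncated normal
#' `Normal(fragment_length_mean, fragment_length_sd)` restricted to
#' `length_bounds`, and spans `[dyad - len/2, dyad + len/2)` clipped to the
#' chromosome. Output is sorted and deterministic given the seed.
#'
#' @param map `NucleosomeMap`.
#' @param condition condition id (column of the weight matrix).
#' @param depth number of fragments to draw.
#' @param spec `SimulationSpec`.
#' @param seed optional explicit seed; defaults to a stream derived from
#'   `spec$seed` and the condition's position.
#' @return `FragmentSet`.
#' @export
simulate_fragments <- function(map, condition, depth, spec, seed = NULL) {
  ci <- match(condition, map$conditions)
  if (is.na(ci)) stopf("unknown condition %s", condition)
  w <- map$weights[, ci]
  if (sum(w) <= 0) stopf("no nucleosome signal for condition %s", condition)
  set.seed(seed %||% (.stage_seed(spec, "fragments") + 1000L * ci))
  chrom_order <- names(map$chrom_lengths)
  if (depth == 0) {
    return(fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer()), chrom_order))
  }
  i <- sample.int(length(w), depth, replace = TRUE, prob = w)
  pos <- map$dyads$pos[i]
  if (spec$dyad_jitter_sd > 0) {
    pos <- pos + round(stats::rnorm(depth, 0, spec$dyad_jitter_sd))
  }
  len <- round(stats::rnorm(depth, spec$fragment_length_mean, spec$fragment_length_sd))
  bad <- len < spec$length_bounds[1] | len > spec$length_bounds[2]
  while (any(bad)) {   # truncation by rejection, not clamping
    len[bad] <- round(stats::rnorm(sum(bad), spec$fragment_length_mean,
                                   spec$fragment_length_sd))
    bad <- len < spec$length_bounds[1] | len > spec$length_bounds[2]
  }
  chrom <- map$dyads$chrom[i]
  L <- unname(map$chrom_lengths[chrom])
  start <- pmax(as.integer(pos - len %/% 2), 0L)
  end <- pmin(as.integer(start + len), L)
  start <- pmin(start, end - 1L)   # keep >= 1 bp after clipping at the edge
  fragment_set(data.frame(chrom = chrom, start = start, end = end), chrom_order)
}

#' Choose window-aligned intervals clear of TSS structure for planting
#'
#' Deterministically selects `n` full-width windows of a grid whose span stays
#' at least `min_tss_dist` bp away from every TSS, evenly spread over the
#' candidates. Planting effects into such windows keeps the planted fold
#' change unconfounded by NDRs and phased +1/-1 dyads.
#'
#' @param grid `WindowGrid`.
#' @param ann `GeneAnnotation`.
#' @param n number of windows to select.
#' @param min_tss_dist minimum distance (bp) between the window span and any
#'   TSS (default 1000).
#' @return data frame `chrom`, `start`, `end` of the selected windows.
#' @export
select_planted_windows <- function(grid, ann, n, min_tss_dist = 1000L) {
  tab <- window_table(grid)
  full <- (tab$end - tab$start) == grid$width
  clear <- full
  for (i in which(full)) {
    tss <- ann$tss[ann$chrom == tab$chrom[i]]
    if (length(tss) &&
        any(tss > tab$start[i] - min_tss_dist & tss < tab$end[i] + min_tss_dist)) {
      clear[i] <- FALSE
    }
  }
  cand <- which(clear)
  if (length(cand) < n) stopf("only %d candidate windows clear of TSSs", length(cand))
  pick <- cand[round(seq(1, length(cand), length.out = n))]
  out <- tab[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the ground-truth dyad map as TSV
#' @param map `NucleosomeMap`.
#' @param path output TSV: `chrom`, `pos`, one `weight_<condition>` column
#'   per condition.
#' @export
write_dyads_tsv <- function(map, path) {
  tab <- map$dyads
  for (cond in map$conditions) tab[[paste0("weight_", cond)]] <- map$weights[, cond]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write resolved planted effects as BED-like TSV
#' @param map `NucleosomeMap`.
#' @param path output: `chrom`, `start`, `end`, `condition`, `fold`.
#' @export
write_effects_bed <- function(map, path) {
  rows <- lapply(map$effects, function(e)
    data.frame(chrom = e$chrom, start = e$start, end = e$end,
               condition = e$condition, fold = e$fold))
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(), start = integer(), end = integer(),
                         condition = character(), fold = numeric())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs the full generator and writes genome FASTA, genePred annotation, one
#' BED3 fragment file per condition, and the ground truth (dyad TSV and
#' planted-effect BED) beside them.
#'
#' @param spec `SimulationSpec`.
#' @param outdir output directory (created if needed).
#' @return named list of output paths, plus the in-memory objects
#'   (`genome`, `annotation`, `map`, `fragments`).
#' @export
simulate_dataset <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(spec)
  ann <- simulate_annotation(genome, spec)
  map <- plant_nucleosome_map(genome, ann, spec)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                annotation = file.path(outdir, "annotation.genePred"),
                dyads = file.path(outdir, "truth_dyads.tsv"),
                effects = file.path(outdir, "truth_effects.bed"))
  write_genome_fasta(genome, paths$genome)
  write_annotation_genepred(ann, paths$annotation)
  write_dyads_tsv(map, paths$dyads)
  write_effects_bed(map, paths$effects)
  frags <- list()
  for (cond in spec$conditions) {
    fs <- simulate_fragments(map, cond, spec$depth, spec)
    paths[[paste0("fragments_", cond)]] <- file.path(outdir, sprintf("fragments_%s.bed", cond))
    write_fragments_bed(fs, paths[[paste0("fragments_", cond)]])
    frags[[cond]] <- fs
  }
  c(paths, list(genome_obj = genome, annotation = ann, map = map, fragments = frags))
}
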
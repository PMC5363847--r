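#' Strand-aware TSS metaprofile
#'
#' Aggregates fragment midpoints around every TSS into fixed bins on a
#' TSS-relative axis where upstream is always to the left. The anchor is the
#' transcription-start boundary (`tx_start` on `+`, `tx_end` on `-`) and the
#' midpoint is the true fragment center `(start+end)/2`, so mirroring all
#' coordinates and flipping strands leaves the profile bit-identical.
#' Midpoints with relative offset in `[-flank, flank)` are assigned to
#' `2*flank/bin` bins; the per-bin value is
#' `count / (bin_kb * total_fragments/1e6 * n_genes_covering)`, where genes
#' whose flank runs off a chromosome end are counted only for the bins they
#' actually cover, so truncated genes do not dilute edge bins.
#'
#' @param fs `FragmentSet`.
#' @param ann `GeneAnnotation` (>= 1 record).
#' @param genome `GenomeAssembly` (for chromosome bounds).
#' @param flank bp on each side of the TSS (default 1000).
#' @param bin bin width in bp (default 10); must divide `flank`.
#' @return `TssProfile`: list with `offset` (bin centers, bp relative to
#'   TSS), `value` (FPKM-scaled), `counts`, `n_genes_bin`, `n_genes`,
#'   `flank`, `bin`, `total_fragments`.
#' @export
tss_metaprofile <- function(fs, ann, genome, flank = 1000L, bin = 10L) {
  if (nrow(ann) == 0) stopf("empty annotation")
  if (flank %% bin != 0) stopf("flank must be divisible by bin")
  nb <- as.integer(2 * flank / bin)
  r0 <- -flank + (seq_len(nb) - 1L) * bin   # bin lower edges, relative bp
  r1 <- r0 + bin
  counts <- numeric(nb)
  ngene_bin <- integer(nb)
  mids_by_chrom <- lapply(
    stats::setNames(unique(fs$frags$chrom), unique(fs$frags$chrom)),
    function(chrom) {
      k <- fs$frags$chrom == chrom
      sort((fs$frags$start[k] + fs$frags$end[k]) / 2)
    })
  used <- 0L
  for (i in seq_len(nrow(ann))) {
    chrom <- ann$chrom[i]
    if (!(chrom %in% genome$chroms)) next
    L <- genome$lengths[[chrom]]
    plus <- ann$strand[i] == "+"
    a <- if (plus) ann$tx_start[i] else ann$tx_end[i]
    used <- used + 1L
    mids <- mids_by_chrom[[chrom]]
    if (!is.null(mids) && length(mids)) {
      ## rel in [-flank, flank): m in [a-flank, a+flank) on +, (a-flank, a+flank] on -
      if (plus) {
        sel <- mids >= a - flank & mids < a + flank
        rel <- mids[sel] - a
      } else {
        sel <- mids > a - flank & mids <= a + flank
        rel <- a - mids[sel]
      }
      if (length(rel)) {
        b <- floor((rel + flank) / bin) + 1L
        counts <- counts + tabulate(b, nb)
      }
    }
    cov <- if (plus) (a + r0 >= 0) & (a + r1 <= L) else (a - r1 >= 0) & (a - r0 <= L)
    ngene_bin <- ngene_bin + cov
  }
  if (used == 0L) stopf("empty annotation")
  denom <- (bin / 1000) * (fs$total_fragments / 1e6) * ngene_bin
  value <- ifelse(ngene_bin > 0, counts / ifelse(denom > 0, denom, 1), 0)
  if (fs$total_fragments == 0) value <- counts * 0
  structure(list(offset = r0 + bin / 2, value = value, counts = counts,
                 n_genes_bin = ngene_bin, n_genes = used,
                 flank = as.integer(flank), bin = as.integer(bin),
                 total_fragments = fs$total_fragments),
            class = "TssProfile")
}

#' Locate NDR and phased-nucleosome landmarks on a TSS profile
#'
#' The NDR center is the minimum-value bin within `ndr_range`, the +1 peak
#' the maximum within `plus1_range`, the -1 peak the maximum within
#' `minus1_range`; offsets are reported at bin centers and ties break toward
#' the smaller offset.
#'
#' @param p `TssProfile` with nonzero signal.
#' @param ndr_range,plus1_range,minus1_range search ranges in TSS-relative bp
#'   (half-open, applied to bin centers).
#' @return list with `ndr_center`, `plus1_peak`, `minus1_peak` (bp offsets).
#' @export
profile_landmarks <- function(p, ndr_range = c(-300, 100),
                              plus1_range = c(0, 300),
                              minus1_range = c(-400, 0)) {
  if (all(p$value == 0)) stopf("all-zero profile")
  pick <- function(range, fun) {
    k <- which(p$offset >= range[1] & p$offset < range[2])
    if (!length(k)) stopf("landmark search range [%g,%g) has no bins", range[1], range[2])
    p$offset[k[fun(p$value[k])]]
  }
  list(ndr_center = pick(ndr_range, which.min),
       plus1_peak = pick(plus1_range, which.max),
       minus1_peak = pick(minus1_range, which.max))
}

#' GC-quintile occupancy summary
#'
#' Computes each window's GC fraction from the genome sequence (N bases
#' excluded from numerator and denominator; windows with > 50% N dropped),
#' ranks windows by GC, splits them into 5 equal-count groups (stable order;
#' sizes differ by at most 1) and summarizes the FPKM distribution of each
#' group for every condition.
#'
#' @param tracks named list of `OccupancyTrack`s (one per condition) sharing
#'   one grid, conventionally the 500-bp grid.
#' @param genome `GenomeAssembly` with sequence.
#' @return data frame with one row per (quintile, condition): `quintile`,
#'   `n_windows`, `gc_min`, `gc_max`, `condition`, `fpkm_min`, `fpkm_q1`,
#'   `fpkm_median`, `fpkm_q3`, `fpkm_max`, `fpkm_mean`.
#' @export
gc_quintile_summary <- function(tracks, genome) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  grid <- tracks[[1]]$grid
  for (tr in tracks) {
    if (!.same_grid(tr$grid, grid)) stopf("tracks are on different grids")
  }
  tab <- window_table(grid)
  gc <- numeric(nrow(tab)); nf <- numeric(nrow(tab))
  for (chrom in grid$chroms) {
    k <- tab$chrom == chrom
    res <- interval_gc(genome, chrom, tab$start[k], tab$end[k])
    gc[k] <- res$gc; nf[k] <- res$n_frac
  }
  keep <- which(!is.na(gc) & nf <= 0.5)
  if (!length(keep)) stopf("no usable windows (all masked by N)")
  n <- length(keep)
  ord <- order(gc[keep])                      # stable: ties keep window order
  quint <- integer(n)
  quint[ord] <- ceiling(seq_len(n) * 5 / n)   # equal counts +/- 1
  rows <- list()
  for (q in 1:5) {
    qk <- keep[quint == q]
    if (!length(qk)) {   # fewer usable windows than groups
      for (cond in names(tracks)) {
        rows[[length(rows) + 1L]] <- data.frame(
          quintile = q, n_windows = 0L, gc_min = NA_real_, gc_max = NA_real_,
          condition = cond, fpkm_min = NA_real_, fpkm_q1 = NA_real_,
          fpkm_median = NA_real_, fpkm_q3 = NA_real_, fpkm_max = NA_real_,
          fpkm_mean = NA_real_)
      }
      next
    }
    for (cond in names(tracks)) {
      v <- tracks[[cond]]$fpkm[qk]
      qs <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        quintile = q, n_windows = length(qk),
        gc_min = min(gc[qk]), gc_max = max(gc[qk]), condition = cond,
        fpkm_min = qs[1], fpkm_q1 = qs[2], fpkm_median = qs[3],
        fpkm_q3 = qs[4], fpkm_max = qs[5], fpkm_mean = mean(v))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("GcQuintileSummary", "data.frame")
  out
}

#' Export a TSS profile as TSV
#' @param p `TssProfile`.
#' @param path output TSV (offset_bp, value, count, n_genes_covering).
#' @export
write_profile_tsv <- function(p, path) {
  utils::write.table(
    data.frame(offset_bp = p$offset, value = p$value, count = p$counts,
               n_genes_covering = p$n_genes_bin),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
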
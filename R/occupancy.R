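#' Tile the genome into fixed-width windows
#'
#' Windows are `[i*width, min((i+1)*width, L))` per chromosome: all full width
#' except possibly a trailing partial window which keeps its true length.
#'
#' @param genome `GenomeAssembly`.
#' @param width window width in bp (>= 1). The analyses here use 10000 for
#'   coarse bin classification and 500 for differential scanning.
#' @return `WindowGrid`: list with `width`, `chroms`, `lengths`, `n_windows`
#'   per chromosome, global `offsets` and `total_windows`.
#' @export
make_windows <- function(genome, width) {
  stopifnot(width >= 1)
  width <- as.integer(width)
  n <- as.integer(ceiling(genome$lengths / width))
  offsets <- cumsum(c(0L, utils::head(n, -1)))
  structure(list(width = width, chroms = genome$chroms,
                 lengths = genome$lengths,
                 n_windows = stats::setNames(n, genome$chroms),
                 offsets = stats::setNames(offsets, genome$chroms),
                 total_windows = sum(n)),
            class = "WindowGrid")
}

#' Window coordinate table of a grid
#' @param grid `WindowGrid`.
#' @return data frame `chrom`, `start`, `end` in global window order.
#' @export
window_table <- function(grid) {
  out <- lapply(grid$chroms, function(chrom) {
    n <- grid$n_windows[[chrom]]
    s <- (seq_len(n) - 1L) * grid$width
    data.frame(chrom = chrom, start = s,
               end = pmin(s + grid$width, grid$lengths[[chrom]]))
  })
  do.call(rbind, out)
}

#' True window lengths (partial trailing windows included)
#' @param grid `WindowGrid`.
#' @return integer vector, one length per window in global order.
#' @export
window_lengths <- function(grid) {
  unlist(lapply(grid$chroms, function(chrom) {
    n <- grid$n_windows[[chrom]]
    w <- rep.int(grid$width, n)
    w[n] <- grid$lengths[[chrom]] - (n - 1L) * grid$width
    w
  }), use.names = FALSE)
}

.same_grid <- function(a, b) {
  a$width == b$width && identical(a$chroms, b$chroms) &&
    identical(unname(a$lengths), unname(b$lengths))
}

#' Count fragments per window
#'
#' `midpoint` (default) assigns each fragment to the single window containing
#' `floor((start+end)/2)`, conserving total count; `overlap` adds 1 to every
#' window the fragment overlaps.
#'
#' @param fs `FragmentSet`.
#' @param grid `WindowGrid`.
#' @param rule `"midpoint"` or `"overlap"`.
#' @return integer vector of counts in global window order.
#' @export
count_fragments <- function(fs, grid, rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  counts <- integer(grid$total_windows)
  w <- grid$width
  for (chrom in unique(fs$frags$chrom)) {
    if (!(chrom %in% grid$chroms)) {
      warnf("fragments on chromosome %s absent from grid ignored", chrom)
      next
    }
    k <- fs$frags$chrom == chrom
    s <- fs$frags$start[k]; e <- fs$frags$end[k]
    nw <- grid$n_windows[[chrom]]
    off <- grid$offsets[[chrom]]
    if (rule == "midpoint") {
      idx <- ((s + e) %/% 2L) %/% w + 1L
      counts[off + seq_len(nw)] <- counts[off + seq_len(nw)] + tabulate(idx, nw)
    } else {
      f <- s %/% w + 1L
      l <- pmin((e - 1L) %/% w + 1L, nw)
      delta <- tabulate(f, nw) - tabulate(l + 1L, nw)
      counts[off + seq_len(nw)] <- counts[off + seq_len(nw)] + cumsum(delta)
    }
  }
  counts
}

#' FPKM-normalize per-window counts into an occupancy track
#'
#' FPKM per window = `count / ((window_length/1000) * (total_fragments/1e6))`:
#' fragments per kilobase of window per million library fragments. Partial
#' trailing windows use their true length. The denominator is the library
#' total, not the number of assigned fragments.
#'
#' @param counts integer vector from [count_fragments()].
#' @param grid `WindowGrid`.
#' @param total_fragments library size (must be > 0).
#' @return `OccupancyTrack`: list with `grid`, `counts`, `fpkm`,
#'   `total_fragments`.
#' @export
fpkm <- function(counts, grid, total_fragments) {
  if (total_fragments <= 0) stopf("empty library: total_fragments must be > 0")
  stopifnot(length(counts) == grid$total_windows)
  len <- window_lengths(grid)
  structure(list(grid = grid, counts = as.integer(counts),
                 fpkm = counts / ((len / 1000) * (total_fragments / 1e6)),
                 total_fragments = as.integer(total_fragments)),
            class = "OccupancyTrack")
}

#' Compute an occupancy track from fragments in one step
#'
#' @inheritParams count_fragments
#' @return `OccupancyTrack` (FPKM denominator = `fs$total_fragments`).
#' @export
occupancy_track <- function(fs, grid, rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  tr <- fpkm(count_fragments(fs, grid, rule), grid, fs$total_fragments)
  tr$rule <- rule
  tr
}

#' Per-feature fragment ratio table
#'
#' With the `midpoint` rule (default) each fragment contributes to the label
#' at its midpoint base, so percentages sum to 100. With the `overlap` rule
#' each fragment contributes its number of overlapping bases to every label it
#' touches, and percentages are over total fragment-bases.
#'
#' @param fs `FragmentSet`.
#' @param p `FeaturePartition`.
#' @param rule `"midpoint"` or `"overlap"`.
#' @return data frame `label`, `count`, `percent`.
#' @export
region_occupancy_ratio <- function(fs, p, rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  lens <- attr(p, "chrom_lengths")
  tot <- stats::setNames(numeric(length(FEATURE_LABELS)), FEATURE_LABELS)
  for (chrom in unique(fs$frags$chrom)) {
    if (!(chrom %in% p$chrom)) next
    part <- p[p$chrom == chrom, , drop = FALSE]
    k <- fs$frags$chrom == chrom
    s <- fs$frags$start[k]; e <- fs$frags$end[k]
    if (rule == "midpoint") {
      mid <- (s + e) %/% 2L
      lab <- as.character(part$label[findInterval(mid, part$start)])
      cnt <- table(factor(lab, levels = FEATURE_LABELS))
      tot <- tot + as.numeric(cnt)
    } else {
      L <- lens[[chrom]]
      for (lb in FEATURE_LABELS) {
        ind <- integer(L)
        rows <- which(part$label == lb)
        for (r in rows) ind[(part$start[r] + 1L):part$end[r]] <- 1L
        cum <- c(0L, cumsum(ind))
        tot[[lb]] <- tot[[lb]] + sum(cum[e + 1L] - cum[s + 1L])
      }
    }
  }
  data.frame(label = FEATURE_LABELS, count = unname(tot),
             percent = unname(if (sum(tot) > 0) 100 * tot / sum(tot) else tot))
}

#' Export an occupancy track as bedGraph
#' @param track `OccupancyTrack`.
#' @param path output bedGraph (chrom, start, end, FPKM).
#' @export
write_track_bedgraph <- function(track, path) {
  tab <- window_table(track$grid)
  tab$fpkm <- track$fpkm
  utils::write.table(format(tab, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export an occupancy track as TSV with counts
#' @param track `OccupancyTrack`.
#' @param path output TSV (chrom, start, end, count, fpkm).
#' @export
write_track_tsv <- function(track, path) {
  tab <- window_table(track$grid)
  tab$count <- track$counts
  tab$fpkm <- track$fpkm
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
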
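#' Classify windows by occupancy change between two conditions
#'
#' Bin-by-bin comparison of two FPKM tracks on the same grid, in the style of
#' a whole-chromosome heat strip: `increase_a` where condition A is at least
#' `fold` times B (boundary inclusive), `decrease_a` symmetric, `absent`
#' where both FPKM are zero, `other` everywhere else. Categories partition the
#' grid; swapping the tracks swaps `increase_a`/`decrease_a` exactly.
#'
#' @param track_a,track_b `OccupancyTrack`s on an identical `WindowGrid`.
#' @param fold fold-change threshold (> 1); default 1.5 for the coarse 10-kb
#'   view.
#' @return data frame `chrom`, `start`, `end`, `fpkm_a`, `fpkm_b`, `category`.
#' @export
classify_bins <- function(track_a, track_b, fold = 1.5) {
  if (!.same_grid(track_a$grid, track_b$grid)) stopf("tracks are on different grids")
  if (fold <= 1) stopf("fold threshold must be > 1")
  a <- track_a$fpkm; b <- track_b$fpkm
  category <- rep("other", length(a))
  category[a >= fold * b & a > 0] <- "increase_a"
  category[b >= fold * a & b > 0] <- "decrease_a"
  category[a == 0 & b == 0] <- "absent"
  out <- window_table(track_a$grid)
  out$fpkm_a <- a
  out$fpkm_b <- b
  out$category <- factor(category,
                         levels = c("increase_a", "decrease_a", "absent", "other"))
  out
}

#' Default minimum-FPKM threshold for differential selection
#'
#' The FPKM value that 5 fragments produce in one window of the given width in
#' the smaller of the two libraries; selections below it are dominated by shot
#' noise (a 1-vs-0 count is a "two-fold change").
#'
#' @param width window width in bp.
#' @param totals vector of library sizes.
#' @return FPKM threshold.
#' @export
default_min_fpkm <- function(width, totals) {
  5 / ((width / 1000) * (min(totals) / 1e6))
}

#' Select differential windows at a fold-change threshold
#'
#' A window qualifies when `max(a,b)/min(a,b) >= fold` (boundary inclusive)
#' and `max(a,b) >= min_fpkm`; if exactly one value is zero the fold is
#' infinite and the window qualifies subject to `min_fpkm`. Windows with both
#' values zero are never selected.
#'
#' @param track_a,track_b `OccupancyTrack`s on an identical `WindowGrid`.
#' @param fold fold threshold (> 1); default 2 for the 500-bp scan.
#' @param min_fpkm minimum of the larger FPKM; default
#'   [default_min_fpkm()] of the grid width and the two library sizes.
#' @return data frame `chrom`, `start`, `end`, `fpkm_a`, `fpkm_b`,
#'   `direction` (`up_in_a`/`down_in_a`), `fold`; attribute `min_fpkm`.
#' @export
differential_windows <- function(track_a, track_b, fold = 2.0, min_fpkm = NULL) {
  if (!.same_grid(track_a$grid, track_b$grid)) stopf("tracks are on different grids")
  if (fold <= 1) stopf("fold threshold must be > 1")
  min_fpkm <- min_fpkm %||%
    default_min_fpkm(track_a$grid$width,
                     c(track_a$total_fragments, track_b$total_fragments))
  a <- track_a$fpkm; b <- track_b$fpkm
  hi <- pmax(a, b); lo <- pmin(a, b)
  fc <- ifelse(lo == 0, Inf, hi / lo)
  sel <- hi > 0 & hi >= min_fpkm & fc >= fold
  out <- window_table(track_a$grid)[sel, , drop = FALSE]
  out$fpkm_a <- a[sel]
  out$fpkm_b <- b[sel]
  out$direction <- ifelse(a[sel] > b[sel], "up_in_a", "down_in_a")
  out$fold <- fc[sel]
  rownames(out) <- NULL
  attr(out, "min_fpkm") <- min_fpkm
  out
}

#' Map differential windows to genes
#'
#' `scope = "genic"` reports a gene when a selected window overlaps its
#' transcript extended by the strand-aware promoter (promoter + 5'UTR + exon +
#' intron + 3'UTR); `scope = "promoter"` restricts the overlap to the
#' promoter interval alone. Genes are deduplicated; a gene hit by windows in
#' both directions reports both.
#'
#' @param wins data frame from [differential_windows()].
#' @param ann `GeneAnnotation`.
#' @param scope `"genic"` or `"promoter"`.
#' @param promoter_span bp upstream of TSS (default 1000).
#' @return data frame `gene_id`, `directions` (comma-joined), `n_windows`.
#' @export
map_windows_to_genes <- function(wins, ann, scope = c("genic", "promoter"),
                                 promoter_span = 1000L) {
  scope <- match.arg(scope)
  plus <- ann$strand == "+"
  if (scope == "genic") {
    gs <- ifelse(plus, ann$tx_start - promoter_span, ann$tx_start)
    ge <- ifelse(plus, ann$tx_end, ann$tx_end + promoter_span)
  } else {
    gs <- ifelse(plus, ann$tx_start - promoter_span, ann$tx_end)
    ge <- ifelse(plus, ann$tx_start, ann$tx_end + promoter_span)
  }
  gs <- pmax(gs, 0L)
  hits <- list()
  for (chrom in unique(ann$chrom)) {
    gk <- which(ann$chrom == chrom & gs < ge)
    wk <- which(wins$chrom == chrom)
    if (!length(gk) || !length(wk)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = gs[gk] + 1L, end = ge[gk]),
      IRanges::IRanges(start = wins$start[wk] + 1L, end = wins$end[wk]))
    if (!length(ov)) next
    hits[[chrom]] <- data.frame(
      gene_id = ann$gene_id[gk[S4Vectors::queryHits(ov)]],
      direction = wins$direction[wk[S4Vectors::subjectHits(ov)]])
  }
  if (!length(hits)) {
    return(data.frame(gene_id = character(), directions = character(),
                      n_windows = integer()))
  }
  h <- do.call(rbind, hits)
  agg <- lapply(split(h$direction, h$gene_id), function(d) {
    list(directions = paste(sort(unique(d)), collapse = ","),
         n_windows = length(d))
  })
  out <- data.frame(gene_id = names(agg),
                    directions = vapply(agg, `[[`, character(1), "directions"),
                    n_windows = vapply(agg, `[[`, integer(1), "n_windows"))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export differential windows as BED6
#'
#' Name column carries the direction; score is `min(1000, round(100*fold))`
#' (infinite folds score 1000).
#'
#' @param wins data frame from [differential_windows()].
#' @param path output BED6.
#' @param labels optional length-2 character vector replacing
#'   `up_in_a`/`down_in_a` with condition labels, e.g. `c("BF", "SF")` makes
#'   `up_in_a` print as `up_in_BF`.
#' @export
write_diff_bed <- function(wins, path, labels = NULL) {
  name <- wins$direction
  if (!is.null(labels)) {
    name <- ifelse(name == "up_in_a", paste0("up_in_", labels[1]),
                   paste0("up_in_", labels[2]))
  }
  score <- ifelse(is.finite(wins$fold), pmin(1000, round(100 * wins$fold)), 1000)
  bed <- data.frame(wins$chrom, wins$start, wins$end, name, score, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a gene list as TSV (WEGO-style input: one gene per row)
#' @param genes data frame from [map_windows_to_genes()].
#' @param path output TSV.
#' @export
write_gene_list_tsv <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
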
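#' Construct a fragment set
#'
#' A `FragmentSet` holds sorted mononucleosome fragment intervals per
#' chromosome plus the library total used as the FPKM denominator.
#'
#' @param frags data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param chrom_order optional character vector fixing chromosome sort order
#'   (e.g. `genome$chroms`); defaults to first-appearance order.
#' @return `FragmentSet`: list with `frags` (sorted) and `total_fragments`.
#' @export
fragment_set <- function(frags, chrom_order = NULL) {
  frags <- data.frame(chrom = as.character(frags$chrom),
                      start = as.integer(frags$start),
                      end = as.integer(frags$end))
  if (nrow(frags) && any(frags$start >= frags$end)) {
    stopf("fragment with start >= end")
  }
  lev <- chrom_order %||% unique(frags$chrom)
  o <- order(match(frags$chrom, lev), frags$start, frags$end)
  frags <- frags[o, , drop = FALSE]
  rownames(frags) <- NULL
  structure(list(frags = frags, total_fragments = nrow(frags)),
            class = "FragmentSet")
}

#' Read mononucleosome fragments from BED3+
#'
#' Columns beyond the first three are ignored. Records on chromosomes absent
#' from the genome, and records with `start >= end`, are dropped with a
#' warning reporting the counts; surviving intervals are clipped to
#' chromosome bounds and returned sorted.
#'
#' @param path tab-separated BED file, no header.
#' @param genome `GenomeAssembly` defining the chromosome space.
#' @return `FragmentSet`.
#' @export
read_fragments <- function(path, genome) {
  if (!file.exists(path)) stopf("fragment file not found: %s", path)
  if (file.size(path) == 0) {
    return(fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer()),
                        chrom_order = genome$chroms))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", colClasses = "character",
                          fill = TRUE)
  if (ncol(df) < 3) stopf("not a BED3+ file: %s", path)
  df <- data.frame(chrom = df[[1]],
                   start = suppressWarnings(as.integer(df[[2]])),
                   end = suppressWarnings(as.integer(df[[3]])))
  if (anyNA(df$start) || anyNA(df$end)) stopf("non-numeric coordinates in %s", path)
  n_unknown <- sum(!(df$chrom %in% genome$chroms))
  if (n_unknown) {
    warnf("dropped %d fragment(s) on chromosomes absent from genome", n_unknown)
    df <- df[df$chrom %in% genome$chroms, , drop = FALSE]
  }
  n_inv <- sum(df$start >= df$end)
  if (n_inv) {
    warnf("dropped %d fragment(s) with start >= end", n_inv)
    df <- df[df$start < df$end, , drop = FALSE]
  }
  L <- genome$lengths[df$chrom]
  df$start <- pmax(df$start, 0L)
  df$end <- pmin(df$end, unname(L))
  df <- df[df$start < df$end, , drop = FALSE]
  fragment_set(df, chrom_order = genome$chroms)
}

#' Write a fragment set as BED3
#' @param fs `FragmentSet`.
#' @param path output file.
#' @export
write_fragments_bed <- function(fs, path) {
  utils::write.table(fs$frags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Join aligned read pairs into fragments
#'
#' Each properly paired read pair becomes one fragment spanning
#' `[min(starts), max(ends))`. Pairs with mates on different chromosomes, on
#' the same strand, or yielding a fragment length outside `length_bounds`
#' are discarded; the discard counts are attached as attribute `discarded`
#' and reported via a message.
#'
#' @param pairs data frame with columns `chrom1`, `start1`, `end1`, `strand1`,
#'   `chrom2`, `start2`, `end2`, `strand2` (0-based half-open).
#' @param length_bounds inclusive fragment length bounds, default `c(50, 500)`.
#' @param chrom_order optional chromosome order for the output.
#' @return `FragmentSet` with attribute `discarded`
#'   (`c(chrom = , strand = , length = )`).
#' @export
pairs_to_fragments <- function(pairs, length_bounds = c(50L, 500L),
                               chrom_order = NULL) {
  need <- c("chrom1", "start1", "end1", "strand1",
            "chrom2", "start2", "end2", "strand2")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stopf("pairs lack columns: %s", paste(miss, collapse = ", "))
  same_chrom <- pairs$chrom1 == pairs$chrom2
  opp_strand <- pairs$strand1 != pairs$strand2
  st <- pmin(pairs$start1, pairs$start2)
  en <- pmax(pairs$end1, pairs$end2)
  len_ok <- (en - st) >= length_bounds[1] & (en - st) <= length_bounds[2]
  keep <- same_chrom & opp_strand & len_ok
  discarded <- c(chrom = sum(!same_chrom),
                 strand = sum(same_chrom & !opp_strand),
                 length = sum(same_chrom & opp_strand & !len_ok))
  if (sum(discarded)) {
    message(sprintf(
      "pairs_to_fragments: discarded %d pair(s) (%d cross-chromosome, %d same-strand, %d length outside [%d,%d])",
      sum(discarded), discarded[["chrom"]], discarded[["strand"]],
      discarded[["length"]], length_bounds[1], length_bounds[2]))
  }
  fs <- fragment_set(data.frame(chrom = pairs$chrom1[keep],
                                start = st[keep], end = en[keep]),
                     chrom_order = chrom_order)
  attr(fs, "discarded") <- discarded
  fs
}

#' Genome coverage rate of a fragment set
#'
#' Fraction of genome bases covered by at least one fragment (the union of
#' fragment intervals; overlaps count once).
#'
#' @param fs `FragmentSet`.
#' @param genome `GenomeAssembly`.
#' @return fraction in \[0, 1\].
#' @export
coverage_rate <- function(fs, genome) {
  covered <- 0
  for (chrom in unique(fs$frags$chrom)) {
    if (!(chrom %in% genome$chroms)) next
    k <- fs$frags$chrom == chrom
    ir <- IRanges::IRanges(start = fs$frags$start[k] + 1L, end = fs$frags$end[k])
    covered <- covered + sum(IRanges::width(IRanges::reduce(ir)))
  }
  covered / sum(genome$lengths)
}
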
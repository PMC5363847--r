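#' Feature labels of the genome partition
#'
#' Ordered by precedence: when features of overlapping transcripts collide,
#' each base takes the highest-precedence label
#' (promoter > 5'UTR > 3'UTR > exon > intron > intergenic).
#' @export
FEATURE_LABELS <- c("promoter", "utr5", "exon", "intron", "utr3", "intergenic")

## painting order = increasing precedence, so later labels overwrite earlier
.PAINT_ORDER <- c("intron", "exon", "utr3", "utr5", "promoter")

#' Construct a genome assembly
#'
#' Wraps a named [Biostrings::DNAStringSet] with chromosome names and lengths.
#' Sequence is required because downstream GC-content stratification reads it.
#'
#' @param seqs named `DNAStringSet` (or named character vector of sequences).
#' @return `GenomeAssembly` object: list with `seqs`, `chroms`, `lengths`.
#' @export
genome_assembly <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (!methods::is(seqs, "DNAStringSet")) {
    stopf("genome_assembly() needs a named DNAStringSet or character vector")
  }
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stopf("all chromosomes must be named")
  ## FASTA headers may carry descriptions after the identifier
  nm <- vapply(strsplit(nm, "[ \t]"), `[`, character(1), 1L)
  names(seqs) <- nm
  if (anyDuplicated(nm)) stopf("duplicate chromosome names: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  w <- Biostrings::width(seqs)
  if (any(w <= 0)) stopf("zero-length chromosome in assembly")
  structure(list(seqs = seqs, chroms = nm,
                 lengths = stats::setNames(as.integer(w), nm)),
            class = "GenomeAssembly")
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return `GenomeAssembly`.
#' @export
read_genome_fasta <- function(path) {
  genome_assembly(Biostrings::readDNAStringSet(path))
}

#' Write a genome to FASTA
#' @param genome `GenomeAssembly`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path, width = 70L)
  invisible(path)
}

#' Extract genome sequence
#'
#' @param genome `GenomeAssembly`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return uppercase nucleotide string of length `end - start`.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  L <- genome$lengths[[chrom]]
  if (start < 0 || end > L || start >= end) stopf("invalid interval [%d,%d) on %s", start, end, chrom)
  as.character(Biostrings::subseq(genome$seqs[[chrom]], start + 1L, end))
}

#' GC fraction of genomic intervals
#'
#' N bases are excluded from both numerator and denominator; an interval with
#' no non-N base gets `NA`.
#'
#' @param genome `GenomeAssembly`.
#' @param chrom chromosome name.
#' @param starts,ends vectors of 0-based half-open bounds (clipped to the
#'   chromosome).
#' @return list with `gc` (fraction among non-N bases) and `n_frac`
#'   (fraction of N bases).
#' @export
interval_gc <- function(genome, chrom, starts, ends) {
  L <- genome$lengths[[chrom]]
  starts <- pmax(0L, as.integer(starts)); ends <- pmin(L, as.integer(ends))
  if (any(starts >= ends)) stopf("empty interval in interval_gc()")
  v <- Biostrings::Views(genome$seqs[[chrom]], starts + 1L, ends)
  freq <- Biostrings::letterFrequency(v, letters = c("C", "G", "N"))
  len <- ends - starts
  eff <- len - freq[, "N"]
  gc <- ifelse(eff > 0, (freq[, "C"] + freq[, "G"]) / eff, NA_real_)
  list(gc = as.numeric(gc), n_frac = as.numeric(freq[, "N"] / len))
}

#' Construct a gene annotation
#'
#' Validates transcript records and computes the strand-aware TSS
#' (`txStart` on `+`, `txEnd - 1` on `-`).
#'
#' @param df data frame with columns `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end` and list-columns `exon_starts`,
#'   `exon_ends` (0-based half-open).
#' @return `GeneAnnotation` (a data frame with an added `tss` column).
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("annotation lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(df)) {
    stopifnot(all(df$strand %in% c("+", "-")),
              all(df$tx_start < df$tx_end),
              all(df$cds_start <= df$cds_end),
              all(df$cds_start >= df$tx_start & df$cds_end <= df$tx_end))
    ok <- mapply(function(s, e, ts, te) {
      length(s) == length(e) && length(s) >= 1L &&
        all(s < e) && !is.unsorted(s, strictly = TRUE) &&
        all(utils::head(e, -1) <= utils::tail(s, -1)) &&
        s[1] >= ts && e[length(e)] <= te
    }, df$exon_starts, df$exon_ends, df$tx_start, df$tx_end)
    if (!all(ok)) stopf("invalid exon structure in records: %s",
                        paste(df$gene_id[!ok], collapse = ", "))
  }
  df$tss <- ifelse(df$strand == "+", df$tx_start, df$tx_end - 1L)
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Load a genePred-format gene annotation
#'
#' Parses the 10-column UCSC genePred layout (name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds; coordinates
#' 0-based half-open). Records with `txStart >= txEnd` are dropped with a
#' warning; structurally broken lines raise a parse error naming the line.
#'
#' @param path genePred/refFlat-style TSV (whitespace-separated accepted).
#' @param genome optional `GenomeAssembly`; records on chromosomes absent from
#'   it are dropped with a warning.
#' @return `GeneAnnotation`.
#' @export
load_annotation <- function(path, genome = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- gene_annotation(data.frame(
    gene_id = character(), chrom = character(), strand = character(),
    tx_start = integer(), tx_end = integer(),
    cds_start = integer(), cds_end = integer(),
    exon_starts = I(list()), exon_ends = I(list())))
  if (!length(lines)) return(empty)

  fields <- strsplit(trimws(lines), "[ \t]+")
  parse_ints <- function(x) suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    if (length(f) < 10L) stopf("malformed genePred line %d: expected 10 fields, got %d",
                               lineno[i], length(f))
    num <- suppressWarnings(as.integer(f[4:8]))
    es <- parse_ints(f[9]); ee <- parse_ints(f[10])
    if (anyNA(num) || anyNA(es) || anyNA(ee)) {
      stopf("malformed genePred line %d: non-numeric coordinate", lineno[i])
    }
    if (length(es) != num[5] || length(ee) != num[5]) {
      stopf("malformed genePred line %d: exonCount %d does not match block lists",
            lineno[i], num[5])
    }
    recs[[i]] <- list(gene_id = f[1], chrom = f[2], strand = f[3],
                      tx_start = num[1], tx_end = num[2],
                      cds_start = num[3], cds_end = num[4],
                      exon_starts = es, exon_ends = ee, line = lineno[i])
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
  lineno <- vapply(recs, `[[`, integer(1), "line")

  bad <- df$tx_start >= df$tx_end
  if (any(bad)) {
    warnf("dropped %d record(s) with txStart >= txEnd (lines %s)",
          sum(bad), paste(lineno[bad], collapse = ", "))
    df <- df[!bad, , drop = FALSE]; lineno <- lineno[!bad]
  }
  bad <- !(df$strand %in% c("+", "-"))
  if (any(bad)) stopf("malformed genePred line %d: strand must be + or -", lineno[bad][1])

  ## structural checks: report as parse errors naming the first offending line
  for (i in seq_len(nrow(df))) {
    s <- df$exon_starts[[i]]; e <- df$exon_ends[[i]]
    ok <- length(s) >= 1L && all(s < e) && !is.unsorted(s, strictly = TRUE) &&
      all(utils::head(e, -1) <= utils::tail(s, -1)) &&
      s[1] >= df$tx_start[i] && e[length(e)] <= df$tx_end[i] &&
      df$cds_start[i] <= df$cds_end[i] &&
      df$cds_start[i] >= df$tx_start[i] && df$cds_end[i] <= df$tx_end[i]
    if (!ok) stopf("malformed genePred line %d: inconsistent exon/CDS structure", lineno[i])
  }
  if (!is.null(genome)) {
    unk <- !(df$chrom %in% genome$chroms)
    if (any(unk)) {
      warnf("dropped %d record(s) on chromosome(s) absent from genome: %s",
            sum(unk), paste(unique(df$chrom[unk]), collapse = ", "))
      df <- df[!unk, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  gene_annotation(df)
}

#' Write an annotation in genePred format
#' @param ann `GeneAnnotation`.
#' @param path output TSV.
#' @export
write_annotation_genepred <- function(ann, path) {
  lines <- vapply(seq_len(nrow(ann)), function(i) {
    paste(ann$gene_id[i], ann$chrom[i], ann$strand[i],
          ann$tx_start[i], ann$tx_end[i], ann$cds_start[i], ann$cds_end[i],
          length(ann$exon_starts[[i]]),
          paste0(paste(ann$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(ann$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## -- interval micro-helpers on 0-based half-open (start, end) matrices --------

.iv <- function(s, e) cbind(start = as.integer(s), end = as.integer(e))

.iv_intersect <- function(iv, a, b) {
  s <- pmax(iv[, 1], a); e <- pmin(iv[, 2], b)
  k <- s < e
  .iv(s[k], e[k])
}

## complement of sorted non-overlapping iv within [a, b)
.iv_complement <- function(iv, a, b) {
  if (!nrow(iv)) return(.iv(a, b))
  s <- c(a, iv[, 2]); e <- c(iv[, 1], b)
  k <- s < e
  .iv(s[k], e[k])
}

#' Derive the exclusive per-base feature partition
#'
#' Labels every base of the genome with exactly one of
#' promoter / 5'UTR / exon / intron / 3'UTR / intergenic. The promoter is
#' `promoter_span` bp immediately upstream of the TSS (strand-aware, clipped
#' at chromosome ends); 5'UTR is exonic sequence between the transcript start
#' side and the CDS start (3'UTR symmetric); `exon` keeps the CDS-overlapping
#' exonic bases; intron is intragenic non-exonic sequence. Overlaps (within or
#' between transcripts) resolve by precedence
#' promoter > utr5 > utr3 > exon > intron > intergenic, so ratios sum to 100%.
#' Non-coding transcripts (`cds_start == cds_end`) have all exonic bases
#' labeled `exon`.
#'
#' @param ann `GeneAnnotation`.
#' @param genome `GenomeAssembly`.
#' @param promoter_span bp upstream of TSS counted as promoter (default 1000).
#' @return `FeaturePartition`: data frame (`chrom`, `start`, `end`, `label`)
#'   whose intervals tile each chromosome exactly.
#' @export
derive_feature_partition <- function(ann, genome, promoter_span = 1000L) {
  stopifnot(promoter_span > 0)
  unk <- !(ann$chrom %in% genome$chroms)
  if (any(unk)) {
    warnf("dropped %d annotation record(s) on chromosome(s) absent from genome",
          sum(unk))
    ann <- ann[!unk, , drop = FALSE]
  }
  code <- stats::setNames(seq_along(FEATURE_LABELS), FEATURE_LABELS)
  out <- vector("list", length(genome$chroms))
  for (ci in seq_along(genome$chroms)) {
    chrom <- genome$chroms[ci]
    L <- genome$lengths[[chrom]]
    lab <- rep.int(code[["intergenic"]], L)
    recs <- ann[ann$chrom == chrom, , drop = FALSE]
    ivs <- stats::setNames(vector("list", length(.PAINT_ORDER)), .PAINT_ORDER)
    for (i in seq_len(nrow(recs))) {
      ex <- .iv(recs$exon_starts[[i]], recs$exon_ends[[i]])
      txs <- recs$tx_start[i]; txe <- recs$tx_end[i]
      cs <- recs$cds_start[i]; ce <- recs$cds_end[i]
      plus <- recs$strand[i] == "+"
      coding <- cs < ce
      if (coding) {
        up <- .iv_intersect(ex, txs, cs)      # exonic upstream of CDS (genomic)
        dn <- .iv_intersect(ex, ce, txe)      # exonic downstream of CDS
        exon_iv <- .iv_intersect(ex, cs, ce)
        utr5 <- if (plus) up else dn
        utr3 <- if (plus) dn else up
      } else {
        exon_iv <- ex
        utr5 <- utr3 <- .iv(integer(), integer())
      }
      intron <- .iv_complement(ex, txs, txe)
      prom <- if (plus) .iv(max(0L, txs - promoter_span), txs)
              else .iv(txe, min(L, txe + promoter_span))
      prom <- prom[prom[, 1] < prom[, 2], , drop = FALSE]
      ivs$intron[[length(ivs$intron) + 1L]] <- intron
      ivs$exon[[length(ivs$exon) + 1L]] <- exon_iv
      ivs$utr3[[length(ivs$utr3) + 1L]] <- utr3
      ivs$utr5[[length(ivs$utr5) + 1L]] <- utr5
      ivs$promoter[[length(ivs$promoter) + 1L]] <- prom
    }
    for (lb in .PAINT_ORDER) {
      for (m in ivs[[lb]]) {
        if (is.null(m) || !nrow(m)) next
        for (r in seq_len(nrow(m))) {
          lab[(m[r, 1] + 1L):m[r, 2]] <- code[[lb]]
        }
      }
    }
    rl <- rle(lab)
    e <- cumsum(rl$lengths)
    out[[ci]] <- data.frame(chrom = chrom,
                            start = c(0L, utils::head(e, -1)),
                            end = e,
                            label = FEATURE_LABELS[rl$values])
  }
  p <- do.call(rbind, out)
  p$label <- factor(p$label, levels = FEATURE_LABELS)
  attr(p, "chrom_lengths") <- genome$lengths
  attr(p, "promoter_span") <- as.integer(promoter_span)
  class(p) <- c("FeaturePartition", "data.frame")
  p
}

#' Genome-fraction table of a feature partition
#'
#' @param p `FeaturePartition`.
#' @return data frame `label`, `bases`, `percent` (percentages sum to 100).
#' @export
compute_genome_ratios <- function(p) {
  w <- p$end - p$start
  bases <- vapply(FEATURE_LABELS, function(lb) sum(w[p$label == lb]), numeric(1))
  data.frame(label = FEATURE_LABELS,
             bases = unname(bases),
             percent = unname(100 * bases / sum(bases)))
}

#' Export a partition as BED4
#' @param p `FeaturePartition`.
#' @param path output BED (chrom, start, end, label).
#' @export
write_partition_bed <- function(p, path) {
  utils::write.table(p[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a label/bases/percent ratio table as TSV
#' @param tab data frame with columns `label`, `bases`, `percent`.
#' @param path output TSV with header `label<TAB>bases<TAB>percent`.
#' @export
write_ratio_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
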
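#' Configuration for an end-to-end two-condition comparison
#'
#' @param genome path to the genome FASTA.
#' @param annotation path to the genePred annotation.
#' @param fragments named list/vector of exactly two BED3 paths; names are
#'   the condition labels (first = condition A in all outputs).
#' @param outdir output directory.
#' @param widths two window widths in bp: coarse bin classification and fine
#'   differential scan (defaults 10000 and 500).
#' @param folds fold thresholds paired with `widths` (defaults 1.5 and 2).
#' @param promoter_span promoter length upstream of TSS in bp.
#' @param flank,profile_bin TSS metaprofile half-width and bin (bp).
#' @param min_fpkm minimum-FPKM filter for differential selection;
#'   `NULL` = [default_min_fpkm()].
#' @param rule fragment-to-window assignment rule, `"midpoint"` or
#'   `"overlap"`.
#' @param seed seed recorded in the manifest (the comparison itself is
#'   deterministic; the seed matters only if inputs are subsampled upstream).
#' @return `RunConfig`.
#' @export
run_config <- function(genome, annotation, fragments, outdir,
                       widths = c(10000L, 500L), folds = c(1.5, 2.0),
                       promoter_span = 1000L, flank = 1000L, profile_bin = 10L,
                       min_fpkm = NULL, rule = "midpoint", seed = 1L) {
  fragments <- as.list(fragments)
  if (length(fragments) != 2 || is.null(names(fragments)) || any(!nzchar(names(fragments)))) {
    stopf("fragments must be a named list of exactly two BED paths")
  }
  stopifnot(all(widths > 0), all(folds > 1), promoter_span > 0,
            flank > 0, profile_bin > 0, flank %% profile_bin == 0)
  structure(list(genome = genome, annotation = annotation,
                 fragments = fragments, labels = names(fragments),
                 outdir = outdir, widths = as.integer(widths), folds = folds,
                 promoter_span = as.integer(promoter_span),
                 flank = as.integer(flank), profile_bin = as.integer(profile_bin),
                 min_fpkm = min_fpkm, rule = rule, seed = as.integer(seed)),
            class = "RunConfig")
}

.relabel_direction <- function(direction, labels) {
  ifelse(direction == "up_in_a", paste0("up_in_", labels[1]),
         paste0("up_in_", labels[2]))
}

#' Run the full two-condition occupancy comparison
#'
#' Loads genome, annotation and both fragment sets, then produces every
#' output of the analysis: per-condition coverage rates; coarse-bin
#' fold-change classification with category counts; fine-window differential
#' selection in both directions; the feature-ratio table (genome % vs
#' per-condition fragment %); the GC-quintile occupancy summary; per-condition
#' TSS metaprofiles with NDR/+1/-1 landmarks; and genic- and promoter-scope
#' differential gene lists. A JSON manifest records parameters, input
#' checksums and output paths. Deterministic given the inputs.
#'
#' @param cfg `RunConfig`.
#' @return the manifest (invisibly); all tables are written under
#'   `cfg$outdir`.
#' @export
run_compare <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  stage <- "load inputs"
  manifest <- list(parameters = cfg[setdiff(names(cfg), "outdir")],
                   inputs = list(), outputs = list(), complete = FALSE)
  tryCatch({
    genome <- read_genome_fasta(cfg$genome)
    ann <- load_annotation(cfg$annotation, genome)
    fsets <- lapply(cfg$fragments, read_fragments, genome = genome)
    manifest$inputs <- lapply(c(list(genome = cfg$genome, annotation = cfg$annotation),
                                cfg$fragments),
                              function(p) list(path = p,
                                               md5 = unname(tools::md5sum(p))))

    stage <- "coverage"
    cov <- vapply(fsets, coverage_rate, numeric(1), genome = genome)
    cov_tab <- data.frame(condition = cfg$labels,
                          total_fragments = vapply(fsets, `[[`, numeric(1), "total_fragments"),
                          coverage_rate = unname(cov))
    utils::write.table(cov_tab, out("coverage.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    stage <- "feature partition"
    part <- derive_feature_partition(ann, genome, cfg$promoter_span)
    gr <- compute_genome_ratios(part)
    ratio_tab <- data.frame(label = gr$label, genome_percent = gr$percent)
    for (i in 1:2) {
      rr <- region_occupancy_ratio(fsets[[i]], part, cfg$rule)
      ratio_tab[[paste0("percent_", cfg$labels[i])]] <- rr$percent
    }
    utils::write.table(ratio_tab, out("region_ratios.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_partition_bed(part, out("partition.bed"))

    stage <- "coarse bin classification"
    grid_coarse <- make_windows(genome, cfg$widths[1])
    tracks_coarse <- lapply(fsets, occupancy_track, grid = grid_coarse, rule = cfg$rule)
    bins <- classify_bins(tracks_coarse[[1]], tracks_coarse[[2]], cfg$folds[1])
    names(bins)[names(bins) == "fpkm_a"] <- paste0("fpkm_", cfg$labels[1])
    names(bins)[names(bins) == "fpkm_b"] <- paste0("fpkm_", cfg$labels[2])
    utils::write.table(bins, out("bins_classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cat_counts <- as.data.frame(table(bins$category))
    names(cat_counts) <- c("category", "n_windows")
    utils::write.table(cat_counts, out("bins_category_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "differential windows"
    grid_fine <- make_windows(genome, cfg$widths[2])
    tracks_fine <- lapply(fsets, occupancy_track, grid = grid_fine, rule = cfg$rule)
    wins <- differential_windows(tracks_fine[[1]], tracks_fine[[2]],
                                 cfg$folds[2], cfg$min_fpkm)
    wtab <- wins
    wtab$direction <- .relabel_direction(wtab$direction, cfg$labels)
    utils::write.table(wtab, out("differential_windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_diff_bed(wins, out("differential_windows.bed"), labels = cfg$labels)
    dir_counts <- data.frame(
      direction = paste0("up_in_", cfg$labels),
      n_windows = c(sum(wins$direction == "up_in_a"),
                    sum(wins$direction == "down_in_a")))
    utils::write.table(dir_counts, out("differential_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "GC quintiles"
    names(tracks_fine) <- cfg$labels
    gc_tab <- gc_quintile_summary(tracks_fine, genome)
    utils::write.table(gc_tab, out("gc_quintiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "TSS profiles"
    landmarks <- list()
    if (nrow(ann)) {
      for (i in 1:2) {
        p <- tss_metaprofile(fsets[[i]], ann, genome, cfg$flank, cfg$profile_bin)
        write_profile_tsv(p, out(sprintf("tss_profile_%s.tsv", cfg$labels[i])))
        lm <- profile_landmarks(p)
        landmarks[[cfg$labels[i]]] <- lm
      }
      lm_tab <- data.frame(condition = cfg$labels,
                           ndr_center = vapply(landmarks, `[[`, numeric(1), "ndr_center"),
                           plus1_peak = vapply(landmarks, `[[`, numeric(1), "plus1_peak"),
                           minus1_peak = vapply(landmarks, `[[`, numeric(1), "minus1_peak"))
      utils::write.table(lm_tab, out("tss_landmarks.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    stage <- "gene lists"
    genes_genic <- map_windows_to_genes(wins, ann, "genic", cfg$promoter_span)
    genes_prom <- map_windows_to_genes(wins, ann, "promoter", cfg$promoter_span)
    for (g in list(list(genes_genic, "genes_genic.tsv"),
                   list(genes_prom, "genes_promoter.tsv"))) {
      tab <- g[[1]]
      tab$directions <- vapply(strsplit(tab$directions, ","), function(d)
        paste(.relabel_direction(d, cfg$labels), collapse = ","), character(1))
      write_gene_list_tsv(tab, out(g[[2]]))
    }

    stage <- "manifest"
    outputs <- c("coverage.tsv", "region_ratios.tsv", "partition.bed",
                 "bins_classification.tsv", "bins_category_counts.tsv",
                 "differential_windows.tsv", "differential_windows.bed",
                 "differential_counts.tsv", "gc_quintiles.tsv",
                 "genes_genic.tsv", "genes_promoter.tsv")
    if (nrow(ann)) {
      outputs <- c(outputs, sprintf("tss_profile_%s.tsv", cfg$labels),
                   "tss_landmarks.tsv")
    }
    manifest$outputs <- stats::setNames(as.list(file.path(cfg$outdir, outputs)), outputs)
    manifest$summary <- list(
      coverage_rate = stats::setNames(as.list(unname(cov)), cfg$labels),
      bin_category_counts = stats::setNames(as.list(cat_counts$n_windows),
                                            as.character(cat_counts$category)),
      differential_window_counts = stats::setNames(as.list(dir_counts$n_windows),
                                                   dir_counts$direction),
      min_fpkm = attr(wins, "min_fpkm"),
      n_genes_genic = nrow(genes_genic),
      n_genes_promoter = nrow(genes_prom))
    manifest$complete <- TRUE
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    invisible(manifest)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
}
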
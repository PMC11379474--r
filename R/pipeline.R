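#' Run the full fasting-refeeding analysis on a dataset
#'
#' Orchestrates the stages in dependency order on a dataset with the layers
#' produced by [simulate_refeeding_dataset()] (or assembled from real
#' inputs): pairwise contrasts and regulation calls for genes and peaks,
#' fasting-regulated universes, k-means pattern discovery, kinetic pattern
#' calls, enhancer classification, nearest-gene links and proximal-enhancer
#' fractions, and bivariate footprinting between Adlib and Refed_24h.
#' All outputs are written as TSV under `outdir` together with a JSON run
#' manifest recording parameters and output checksums.
#'
#' @param dataset A `refeed_dataset` (or a list with the same layers).
#' @param outdir Output directory (created if missing).
#' @param fc_min,alpha,rpkm_min Thresholds (defaults 1.5 / 0.05 / 1).
#' @param run_footprinting Set FALSE to skip the footprinting stage.
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_refeeding_pipeline <- function(dataset, outdir,
                                   fc_min = 1.5, alpha = 0.05,
                                   rpkm_min = 1, run_footprinting = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  conditions <- conditions_from_sample_ids(colnames(dataset$gene_counts))
  cond_order <- dataset$design$conditions

  # --- genes: contrasts, universes, clustering, kinetic patterns
  de <- run_standard_contrasts(dataset$gene_counts, conditions,
                               fc_min = fc_min, alpha = alpha)
  for (nm in names(de$contrasts))
    data.table::fwrite(de$contrasts[[nm]],
                       file.path(outdir, paste0("contrast_gene_", nm, ".tsv")),
                       sep = "\t")
  universe <- fasting_regulated_universe(de$calls)
  patterns <- call_refeeding_patterns(de$calls)
  data.table::fwrite(patterns, file.path(outdir, "gene_patterns.tsv"),
                     sep = "\t")

  cm <- condition_means(dataset$gene_counts, conditions,
                        de$size_factors, cond_order)
  clustering <- NULL
  if (length(universe$repressed) >= 3) {
    clustering <- cluster_patterns(cm[universe$repressed, , drop = FALSE],
                                   k = 3, seed = dataset$seed)
    data.table::fwrite(
      data.table::data.table(feature_id = names(clustering$assignment),
                             cluster = clustering$assignment),
      file.path(outdir, "clusters_fasting_repressed.tsv"), sep = "\t")
  }

  # --- peaks: contrasts, enhancer classes, nearest genes, fractions
  peak_conditions <- conditions_from_sample_ids(colnames(dataset$peak_counts))
  pde <- run_standard_contrasts(dataset$peak_counts, peak_conditions,
                                fc_min = fc_min, alpha = alpha)
  enhancer_calls <- classify_enhancers(pde$calls)
  data.table::fwrite(enhancer_calls, file.path(outdir, "enhancer_calls.tsv"),
                     sep = "\t")
  links <- nearest_gene(dataset$peaks, dataset$annotation)
  data.table::fwrite(links, file.path(outdir, "enhancer_gene_links.tsv"),
                     sep = "\t")

  overshoot_genes <- patterns$feature_id[patterns$pattern == "E"]
  recovered_genes <- patterns$feature_id[patterns$pattern == "D"]
  activated_peaks <-
    enhancer_calls$peak_id[enhancer_calls$refeeding_activated]
  fractions <- NULL
  if (length(overshoot_genes) > 0 && length(recovered_genes) > 0) {
    fractions <- compare_proximal_fractions(overshoot_genes, recovered_genes,
                                            activated_peaks, links)
    data.table::fwrite(
      data.table::data.table(gene_set = c("overshoot", "recovered"),
                             fraction = c(fractions$fraction_a,
                                          fractions$fraction_b),
                             fisher_p = fractions$p_value),
      file.path(outdir, "proximal_enhancer_fractions.tsv"), sep = "\t")
  }

  # --- footprinting between Adlib and Refed_24h
  footprint <- NULL
  if (run_footprinting && !is.null(dataset$cut_tracks)) {
    tr_a <- scale_track(dataset$cut_tracks[["Adlib"]])
    tr_b <- scale_track(dataset$cut_tracks[["Refed_24h"]])
    st_a <- footprint_stats_all(tr_a, dataset$motifs, dataset$peaks)
    st_b <- footprint_stats_all(tr_b, dataset$motifs, dataset$peaks)
    footprint <- bagfoot_delta(st_a, st_b)
    data.table::fwrite(footprint$deltas,
                       file.path(outdir, "footprint_deltas.tsv"), sep = "\t")
  }

  # --- truth-vs-called confusion matrix when truth labels are available
  confusion <- NULL
  if (!is.null(dataset$gene_truth)) {
    truth <- dataset$gene_truth$pattern
    called <- patterns$pattern[match(dataset$gene_truth$feature_id,
                                     patterns$feature_id)]
    confusion <- table(truth = truth, called = called)
    utils::write.table(as.data.frame(confusion),
                       file.path(outdir, "confusion_matrix.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  params <- list(fc_min = fc_min, alpha = alpha, rpkm_min = rpkm_min,
                 seed = dataset$seed, conditions = cond_order)
  outputs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(parameters = params,
                   outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(de = de, universe = universe, patterns = patterns,
                 clustering = clustering, peak_de = pde,
                 enhancer_calls = enhancer_calls, links = links,
                 fractions = fractions, footprint = footprint,
                 confusion = confusion, manifest = manifest))
}

#' Self-contained demonstration run on synthetic data
#'
#' Generates a synthetic five-condition dataset with planted ground truth and
#' runs the full pipeline on it; deterministic given the seed.
#'
#' @param seed Integer seed (default 17).
#' @param outdir Output directory (default a tempdir subdirectory).
#' @param ... Passed to [simulate_refeeding_dataset()].
#' @return The pipeline result list, with the dataset attached as `dataset`.
#' @export
run_demo <- function(seed = 17L, outdir = file.path(tempdir(), "refeedr_demo"),
                     ...) {
  dataset <- simulate_refeeding_dataset(seed = seed, ...)
  res <- run_refeeding_pipeline(dataset, outdir)
  res$dataset <- dataset
  invisible(res)
}

#' Precision and recall of kinetic pattern calls against truth labels
#'
#' @param patterns Pattern call table from [call_refeeding_patterns()].
#' @param truth Truth table (feature_id, pattern).
#' @param labels Patterns to evaluate (default D, E, F, G).
#' @return data.table pattern, n_truth, n_called, recall, precision.
#' @export
pattern_performance <- function(patterns, truth,
                                labels = c("D", "E", "F", "G")) {
  called <- patterns$pattern[match(truth$feature_id, patterns$feature_id)]
  data.table::rbindlist(lapply(labels, function(lab) {
    tp <- sum(truth$pattern == lab & called == lab, na.rm = TRUE)
    n_truth <- sum(truth$pattern == lab)
    n_called <- sum(called == lab, na.rm = TRUE)
    data.table::data.table(pattern = lab, n_truth = n_truth,
                           n_called = n_called,
                           recall = if (n_truth > 0) tp / n_truth else NA_real_,
                           precision = if (n_called > 0) tp / n_called
                                       else NA_real_)
  }))
}
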
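#!/usr/bin/env Rscript
# Stage 3: fasting-regulated gene universes, k-means pattern discovery on
# the fasting-repressed set (k = 3, one-minus-Pearson), rule-based kinetic
# pattern calls (D recovered, E overshoot, F late, G early), and a
# truth-vs-called confusion matrix.

suppressMessages(library(refeedr))
suppressMessages(library(data.table))

outdir <- "results/patterns"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

calls <- fread("results/diffexpr/gene_calls.tsv")
truth <- fread("results/data/gene_truth.tsv")
counts <- read_counts_tsv("results/data/gene_counts.tsv")
conds <- conditions_from_sample_ids(colnames(counts))

universe <- fasting_regulated_universe(calls)
cat(sprintf("fasting-induced: %d genes; fasting-repressed: %d genes\n",
            length(universe$induced), length(universe$repressed)))
fwrite(data.table(gene_id = universe$induced),
       file.path(outdir, "fasting_induced.tsv"), sep = "\t")
fwrite(data.table(gene_id = universe$repressed),
       file.path(outdir, "fasting_repressed.tsv"), sep = "\t")

sf <- normalize_libraries(counts, method = "tmm")
cm <- condition_means(counts, conds, sf,
                      cond_order = c("Adlib", "Fasted", "Refed_3h",
                                     "Refed_10h", "Refed_24h"))
for (set_name in c("induced", "repressed")) {
  genes <- universe[[set_name]]
  if (length(genes) < 3) next
  cl <- cluster_patterns(cm[genes, , drop = FALSE], k = 3, seed = 17)
  labs <- match_clusters_to_templates(cl)
  fwrite(data.table(gene_id = names(cl$assignment),
                    cluster = cl$assignment,
                    template = labs[as.character(cl$assignment)]),
         file.path(outdir, sprintf("clusters_fasting_%s.tsv", set_name)),
         sep = "\t")
  cat(sprintf("fasting-%s clustering: %s\n", set_name,
              paste(sprintf("cluster %s -> %s (n=%d)", names(labs), labs,
                            tabulate(cl$assignment, 3)), collapse = "; ")))
}

patterns <- call_refeeding_patterns(calls)
fwrite(patterns, file.path(outdir, "pattern_calls.tsv"), sep = "\t")
perf <- pattern_performance(patterns, truth)
fwrite(perf, file.path(outdir, "pattern_performance.tsv"), sep = "\t")
cat("\npattern recovery against planted truth:\n")
print(perf)

confusion <- table(truth = truth$pattern,
                   called = patterns$pattern[match(truth$feature_id,
                                                   patterns$feature_id)])
write.table(as.data.frame(confusion), file.path(outdir, "confusion.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
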
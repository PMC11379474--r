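#!/usr/bin/env Rscript
# Stage 5: enhancer kinetic classification (overshoot / recovered /
# refeeding-activated), nearest-gene linkage, and the proximal-enhancer
# fraction comparison between overshoot and recovered genes.

suppressMessages(library(refeedr))
suppressMessages(library(data.table))

outdir <- "results/enhancers"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

peak_calls <- fread("results/diffexpr/peak_calls.tsv")
peaks <- read_bed("results/data/peaks.bed")
setnames(peaks, "name", "peak_id")
ann <- fread("results/data/gene_annotation.tsv")
patterns <- fread("results/patterns/pattern_calls.tsv")

enh <- classify_enhancers(peak_calls)
fwrite(enh, file.path(outdir, "enhancer_calls.tsv"), sep = "\t")
cat("enhancer classes:\n")
print(enh[, .N, by = kinetic_pattern])
cat(sprintf("refeeding-activated enhancers: %d\n",
            sum(enh$refeeding_activated)))

links <- nearest_gene(peaks, ann)
fwrite(links, file.path(outdir, "gene_links.tsv"), sep = "\t")

overshoot_genes <- patterns[pattern == "E", feature_id]
recovered_genes <- patterns[pattern == "D", feature_id]
activated <- enh[refeeding_activated == TRUE, peak_id]
cmp <- compare_proximal_fractions(overshoot_genes, recovered_genes,
                                  activated, links)
fwrite(data.table(gene_set = c("overshoot", "recovered"),
                  n_genes = c(length(overshoot_genes),
                              length(recovered_genes)),
                  fraction_with_enhancer = c(cmp$fraction_a, cmp$fraction_b),
                  fisher_p = cmp$p_value),
       file.path(outdir, "proximal_fractions.tsv"), sep = "\t")
cat(sprintf("\nproximal refeeding-activated enhancer: %.1f%% of overshoot genes vs %.1f%% of recovered genes (Fisher p = %.2g)\n",
            100 * cmp$fraction_a, 100 * cmp$fraction_b, cmp$p_value))

# occupancy of the Refed_24h cut signal at the two enhancer classes
track <- scale_track(read_bedgraph("results/data/cuts_Refed_24h.bedGraph",
                                   contigs = c(chrS = 1e7L)))
classes <- list(
  overshoot = peaks[peak_id %in% enh[kinetic_pattern == "overshoot", peak_id]],
  recovered = peaks[peak_id %in% enh[kinetic_pattern == "recovered", peak_id]])
classes <- classes[vapply(classes, nrow, 0L) > 0]
if (length(classes) >= 1) {
  occ <- occupancy_at_classes(track, classes, baseline = peaks)
  fwrite(occ$summary, file.path(outdir, "occupancy_summary.tsv"), sep = "\t")
  fwrite(occ$tests, file.path(outdir, "occupancy_tests.tsv"), sep = "\t")
  cat("\nwindowed occupancy (ATAC cuts, Refed_24h):\n")
  print(occ$summary)
}
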
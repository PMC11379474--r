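#!/usr/bin/env Rscript
# Stage 1: generate the synthetic five-condition fasting/refeeding dataset
# with planted ground truth and write every layer to disk in standard
# formats (counts TSV, annotation TSV, peaks BED, motif BED, cut bedGraphs,
# truth TSV). Downstream stages read only these files.

suppressMessages(library(refeedr))
suppressMessages(library(data.table))

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 17L

ds <- simulate_refeeding_dataset(seed = seed)

write_counts_tsv(ds$gene_counts, file.path(outdir, "gene_counts.tsv"))
write_counts_tsv(ds$peak_counts, file.path(outdir, "peak_counts.tsv"))
fwrite(ds$annotation, file.path(outdir, "gene_annotation.tsv"), sep = "\t")
fwrite(ds$gene_truth, file.path(outdir, "gene_truth.tsv"), sep = "\t")
fwrite(ds$peak_truth, file.path(outdir, "peak_truth.tsv"), sep = "\t")
fwrite(ds$truth_linkage, file.path(outdir, "truth_linkage.tsv"), sep = "\t")
write_bed(ds$peaks[, .(chrom, start, end, name = peak_id)],
          file.path(outdir, "peaks.bed"))
write_bed(ds$motifs[, .(chrom, start, end, name = motif_id, strand)],
          file.path(outdir, "motifs.bed"))
for (cond in names(ds$cut_tracks))
  write_bedgraph(ds$cut_tracks[[cond]],
                 file.path(outdir, sprintf("cuts_%s.bedGraph", cond)))

cat(sprintf("simulated %d genes (%d per kinetic pattern D-G), %d peaks, %d motif occurrences\n",
            nrow(ds$gene_counts), sum(ds$gene_truth$pattern == "E"),
            nrow(ds$peaks), nrow(ds$motifs)))
cat("wrote", outdir, "\n")
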
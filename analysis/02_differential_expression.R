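#!/usr/bin/env Rscript
# Stage 2: pairwise NB Wald contrasts for genes and peaks with the study
# cutoffs (FC >= 1.5, BH-adjusted p <= 0.05), written one TSV per contrast
# plus a combined regulation-call table.

suppressMessages(library(refeedr))
suppressMessages(library(data.table))

indir <- "results/data"
outdir <- "results/diffexpr"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

for (layer in c("gene", "peak")) {
  counts <- read_counts_tsv(file.path(indir, sprintf("%s_counts.tsv", layer)))
  conds <- conditions_from_sample_ids(colnames(counts))
  de <- run_standard_contrasts(counts, conds)
  for (nm in names(de$contrasts)) {
    out <- merge(de$contrasts[[nm]],
                 de$calls[contrast == nm, .(feature_id, status)],
                 by = "feature_id")
    fwrite(out, file.path(outdir, sprintf("%s_%s.tsv", layer, nm)),
           sep = "\t")
  }
  fwrite(de$calls, file.path(outdir, sprintf("%s_calls.tsv", layer)),
         sep = "\t")
  n_reg <- de$calls[, .(n = sum(status != "unchanged")), by = contrast]
  cat(sprintf("[%s] regulated features per contrast:\n", layer))
  print(n_reg)
}
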
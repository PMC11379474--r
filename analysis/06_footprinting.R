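#!/usr/bin/env Rscript
# Stage 6: bivariate footprinting between Adlib and Refed_24h — per-motif
# footprint depth (FPD) and flanking accessibility (FA) across accessible
# sites, condition deltas, bagplot outliers, and known-motif enrichment in
# overshoot enhancers against the whole accessible landscape.

suppressMessages(library(refeedr))
suppressMessages(library(data.table))

outdir <- "results/footprinting"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

peaks <- read_bed("results/data/peaks.bed")
setnames(peaks, "name", "peak_id")
motifs <- read_bed("results/data/motifs.bed")
setnames(motifs, "name", "motif_id")
enh <- fread("results/enhancers/enhancer_calls.tsv")

contigs <- c(chrS = 1e7L)
tr_a <- scale_track(read_bedgraph("results/data/cuts_Adlib.bedGraph", contigs))
tr_b <- scale_track(read_bedgraph("results/data/cuts_Refed_24h.bedGraph",
                                  contigs))
st_a <- footprint_stats_all(tr_a, motifs, peaks)
st_b <- footprint_stats_all(tr_b, motifs, peaks)
bag <- bagfoot_delta(st_a, st_b)
fwrite(bag$deltas, file.path(outdir, "footprint_deltas.tsv"), sep = "\t")
cat("bagplot outliers (Refed_24h minus Adlib):",
    if (length(bag$outliers)) paste(bag$outliers, collapse = ", ")
    else "none", "\n")
top <- bag$deltas[order(-dfpd)][1:3, .(motif_id, dfa, dfpd, outlier)]
cat("largest footprint-depth gains:\n")
print(top)

overshoot_sites <- peaks[peak_id %in% enh[kinetic_pattern == "overshoot",
                                          peak_id]]
if (nrow(overshoot_sites) >= 5) {
  enr <- motif_enrichment(overshoot_sites, peaks, motifs)
  fwrite(enr[order(p_value)], file.path(outdir, "motif_enrichment.tsv"),
         sep = "\t")
  cat("\ntop motif enrichment in overshoot enhancers (landscape background):\n")
  print(enr[order(p_value)][1:3])
}
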
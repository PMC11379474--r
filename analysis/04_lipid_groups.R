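#!/usr/bin/env Rscript
# Stage 4: curation filter and fold-change comparison for lipid-pathway
# gene groups. With no literature lists on the synthetic genome, LIPO-like
# and CHOL-like groups are assembled from the planted truth: overshoot (E)
# genes stand in for lipogenesis, recovered (D) genes for cholesterol
# biosynthesis — mirroring the biology the groups represent.

suppressMessages(library(refeedr))
suppressMessages(library(data.table))

outdir <- "results/lipid_groups"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

truth <- fread("results/data/gene_truth.tsv")
ann <- fread("results/data/gene_annotation.tsv")
calls <- fread("results/diffexpr/gene_calls.tsv")
counts <- read_counts_tsv("results/data/gene_counts.tsv")
conds <- conditions_from_sample_ids(colnames(counts))

set.seed(17)
lipo <- gene_group("LIPO_like", sample(truth[pattern == "E", feature_id], 30),
                   note = "synthetic stand-in: planted overshoot genes")
chol <- gene_group("CHOL_like", sample(truth[pattern == "D", feature_id], 30),
                   note = "synthetic stand-in: planted recovered genes")

rpkm <- compute_rpkm(counts, setNames(ann$length_bp, ann$gene_id))
rpkm_cm <- condition_means(rpkm, conds, rep(1, ncol(rpkm)))
universe <- fasting_regulated_universe(calls)

filtered <- lapply(list(lipo, chol), filter_group, rpkm_cond_means = rpkm_cm,
                   fasting_repressed = universe$repressed)
report <- rbindlist(lapply(filtered, `[[`, "report"))
fwrite(report, file.path(outdir, "filter_report.tsv"), sep = "\t")
cat("curation filter report:\n")
print(report)

cmp <- group_fc_comparison(lapply(filtered, `[[`, "group"),
                           fread("results/diffexpr/gene_Fasted_vs_Adlib.tsv"),
                           fread("results/diffexpr/gene_Refed_24h_vs_Adlib.tsv"))
fwrite(cmp$per_gene, file.path(outdir, "per_gene_fc.tsv"), sep = "\t")
fwrite(cmp$tests, file.path(outdir, "group_tests.tsv"), sep = "\t")
med <- cmp$per_gene[, .(median_repression_fc = median(fasting_repression_fc),
                        median_induction_fc = median(refeeding_induction_fc)),
                    by = group]
cat("\nmedian fold changes per group:\n")
print(med)
cat("\nMann-Whitney comparisons:\n")
print(cmp$tests)
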
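# refeedr

Kinetic analysis of the liver's transcriptional and enhancer response to
fasting and refeeding.

## What this package is for

After a prolonged fast, refeeding does not return the liver to its
pre-fasting state: transcription reorganizes in temporally distinct waves,
and among fasting-repressed genes two fates diverge — **recovered** genes
return to the ad libitum baseline while **overshoot** genes rise
significantly above it. The same kinetic classes appear in enhancer
accessibility, and transcription-factor footprints inside accessible
chromatin deepen where a factor gains occupancy upon refeeding.

`refeedr` implements the complete analysis chain for a five-condition
design (`Adlib`, `Fasted`, `Refed_3h`, `Refed_10h`, `Refed_24h`, three
replicates each):

* **Differential testing** — negative-binomial Wald contrasts (log-link
  GLM, expected-information SE), method-of-moments dispersion with trend
  shrinkage, median-of-ratios or TMM size factors, BH correction per
  contrast, and the regulation rule FC ≥ 1.5 with adjusted p ≤ 0.05
  (boundaries inclusive).
* **Kinetic patterns** — fasting-induced/repressed gene universes
  ("regulated vs at least one fed state"), k-means discovery with a
  one-minus-Pearson metric (k = 3, ≤ 1,000 iterations), and rule-based
  calls for pattern D (recovered), E (overshoot), F (late induction),
  G (early induction), resolved to a partition with precedence D > E > F > G.
* **Lipid gene groups** — the expressed (RPKM ≥ 1) and fasting-repressed
  curation filter, then Mann-Whitney comparison of fasting-repression and
  refeeding-induction fold changes between groups.
* **Enhancers** — overshoot/recovered/refeeding-activated classes under
  the gene cutoffs, nearest-TSS gene linkage with deterministic
  tie-breaks, proximal-enhancer fractions with Fisher tests, and windowed
  occupancy comparisons.
* **Quantification conventions** — tracks scaled to 1e7 total, ±200 bp
  windowed tag counts, ±4 kb/10 bp aggregate profiles, strand-aware
  promoter-proximal annotation (−1 kb/+0.1 kb of TSS).
* **Bivariate footprinting** — per-motif footprint depth (FPD) and
  flanking accessibility (FA), with FA = log2 mean flank density
  (35 < |offset| ≤ 200 bp) and FPD = FA − log2 mean interior density;
  condition deltas summarized in a bagplot built from exact Tukey
  halfspace depths, and hypergeometric motif enrichment against the whole
  accessible landscape.
* **Synthetic data** — an NB count/peak/cut-track generator with planted
  kinetic templates, enhancer-gene linkage, and motif footprints, so every
  stage is validated against known truth.

## Worked example

A self-contained demonstration generates a synthetic dataset (3,300 genes,
200 per kinetic pattern D–G; ~520 enhancer peaks; 20 motifs) and runs every
stage:

```r
library(refeedr)
res <- run_demo(seed = 17, outdir = "demo_out")
pattern_performance(res$patterns, res$dataset$gene_truth)
#>    pattern n_truth n_called recall precision
#> 1:       D     200      203  1.000 0.9852217
#> 2:       E     200      201  0.995 0.9900498
#> 3:       F     200      197  0.980 0.9949239
#> 4:       G     200      203  0.980 0.9655172
```

Every planted pattern is recovered with precision and recall near or above
0.97: of 200 planted overshoot (E) genes, 199 are called E and two called
features are false. The proximal-enhancer comparison mirrors the planted
linkage (60% of overshoot genes were given an adjacent refeeding-activated
enhancer, none of the recovered genes):

```r
res$fractions$fraction_a   # overshoot genes with adjacent activated enhancer
#> [1] 0.5970149
res$fractions$fraction_b   # recovered genes
#> [1] 0
```

and the motif whose footprint was planted to deepen upon refeeding is the
bagplot outlier in the jointly-increased quadrant:

```r
res$footprint$deltas[order(-dfpd)][1, .(motif_id, dfa, dfpd, outlier)]
#>    motif_id        dfa      dfpd outlier
#> 1: motif_01 0.01579536 0.9258557    TRUE
```

(planted ΔFPD = 1: the interior fraction drops from 0.5 to 0.25).

The same chain, written as a narrated file-based workflow, lives in
`analysis/01_simulate.R` … `analysis/06_footprinting.R`; each stage reads
the previous stage's TSV/BED/bedGraph outputs under `results/` and prints
what it found.

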
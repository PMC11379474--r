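# shared fixtures, all generated in code

two_group_design <- function(reps = 3L) {
  study_design(conditions = c("A", "B"), replicates = reps)
}

# regulation-call table from a named status list, one contrast per element
make_calls <- function(feature_id, status_by_contrast) {
  data.table::rbindlist(lapply(names(status_by_contrast), function(nm)
    data.table::data.table(feature_id = feature_id, contrast = nm,
                           status = status_by_contrast[[nm]])))
}

# uniform signal track of one value over [0, len) of a single contig
uniform_track <- function(value = 1, len = 100000L, contig = "chrS") {
  signal_track(
    data.table::data.table(chrom = contig, start = 0L, end = len,
                           value = value),
    contigs = stats::setNames(len, contig))
}

# independent brute-force Tukey depth: minimum over halfplane directions
# defined by all point pairs (plus coordinate axes), counting points with
# non-negative projection
brute_force_depth <- function(xy) {
  n <- nrow(xy)
  dirs <- list(c(1, 0), c(0, 1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- xy[j, ] - xy[i, ]
    nd <- sqrt(sum(d^2))
    if (nd == 0) next
    u <- c(-d[2], d[1]) / nd
    # perturb slightly to both sides of the pair-defined boundary
    for (eps in c(-1e-9, 0, 1e-9)) {
      ang <- atan2(u[2], u[1]) + eps
      dirs[[length(dirs) + 1L]] <- c(cos(ang), sin(ang))
    }
  }
  vapply(seq_len(n), function(k) {
    counts <- vapply(dirs, function(u) {
      proj <- (xy[, 1] - xy[k, 1]) * u[1] + (xy[, 2] - xy[k, 2]) * u[2]
      sum(proj >= -1e-12)
    }, 0)
    min(counts)
  }, 0)
}

# brute-force nearest gene: full distance matrix per chromosome with the
# same tie rule (smaller distance, then lexicographically smaller gene id)
brute_force_nearest <- function(peaks, annotation) {
  centers <- floor((peaks$start + peaks$end) / 2)
  out_gene <- rep(NA_character_, nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    g <- annotation[annotation$chrom == peaks$chrom[p], ]
    if (nrow(g) == 0) next
    d <- abs(centers[p] - g$tss)
    cand <- which(d == min(d))
    out_gene[p] <- sort(g$gene_id[cand])[1]
  }
  out_gene
}
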
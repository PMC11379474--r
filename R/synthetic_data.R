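#' Five-condition feeding study design
#'
#' Describes the Adlib -> Fasted -> Refed_3h/10h/24h paradigm: an ordered set
#' of condition labels with a fixed number of biological replicates each.
#'
#' @param conditions Ordered character vector of condition labels.
#' @param replicates Replicates per condition (>= 2 for any condition used in
#'   a contrast).
#' @param seed Default seed for simulations built on this design.
#' @return An object of class `study_design`.
#' @export
study_design <- function(conditions = c("Adlib", "Fasted", "Refed_3h",
                                        "Refed_10h", "Refed_24h"),
                         replicates = 3L, seed = 17L) {
  if (anyDuplicated(conditions)) stop("condition labels must be unique")
  if (replicates < 2L) stop("need >= 2 replicates per condition")
  structure(list(conditions = as.character(conditions),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Sample sheet for a study design
#'
#' @param design A `study_design`.
#' @return data.table with sample_id, condition, replicate.
#' @export
design_samples <- function(design) {
  dt <- data.table::CJ(condition = design$conditions,
                       replicate = seq_len(design$replicates),
                       sorted = FALSE)
  dt[, condition := factor(condition, levels = design$conditions)]
  data.table::setorder(dt, condition, replicate)
  dt[, condition := as.character(condition)]
  dt[, sample_id := paste0(condition, "_rep", replicate)]
  dt[]
}

#' Kinetic pattern templates
#'
#' Per-condition mean multipliers for the seven kinetic patterns plus a flat
#' null template, in condition order Adlib, Fasted, Refed_3h, Refed_10h,
#' Refed_24h:
#' * A: fasting-induced, waning slowly upon refeeding
#' * B: fasting-induced, back to basal quickly upon refeeding
#' * C: unchanged by fasting, transiently repressed early in refeeding
#' * D: fasting-repressed, recovering to basal ("recovered")
#' * E: fasting-repressed, exceeding basal after refeeding ("overshoot")
#' * F: unchanged by fasting, induced late in refeeding
#' * G: transiently induced early in refeeding
#'
#' Defaults put every intended contrast at least two-fold beyond the 1.5
#' fold-change cutoff so that planted calls are comfortably powered at three
#' replicates; `hard_mode` halves every log2 effect for power studies.
#'
#' @param hard_mode Halve all log2 effect sizes.
#' @return Named list of numeric multiplier vectors (length 5).
#' @export
pattern_templates <- function(hard_mode = FALSE) {
  tpl <- list(
    A    = c(1, 4,    4,   1,   1),
    B    = c(1, 4,    1,   1,   1),
    C    = c(1, 1,    0.25, 1,  1),
    D    = c(1, 0.25, 0.4, 0.8, 1),
    E    = c(1, 0.25, 0.5, 2.5, 3),
    F    = c(1, 1,    1,   3,   3),
    G    = c(1, 1,    3,   1,   1),
    flat = c(1, 1,    1,   1,   1)
  )
  if (hard_mode) tpl <- lapply(tpl, function(m) 2^(log2(m) / 2))
  tpl
}

check_templates <- function(templates, n_cond) {
  for (nm in names(templates)) {
    m <- templates[[nm]]
    if (length(m) != n_cond) stop("template '", nm, "' has wrong length")
    if (any(!is.finite(m)) || any(m <= 0))
      stop("template '", nm, "' has non-positive multipliers")
  }
  invisible(TRUE)
}

#' Simulate negative-binomial counts with planted kinetic patterns
#'
#' Counts for feature i in sample j are NB with mean
#' `base_mean_i * multiplier[template_i, condition_j] * library_factor_j`
#' and variance `mu + dispersion * mu^2`. Base means are drawn log-uniformly
#' from `base_mean_range`.
#'
#' @param design A `study_design`.
#' @param templates Named list of multiplier vectors (see [pattern_templates()]).
#' @param n_per_template Named integer vector: features per template label.
#' @param base_mean_range Positive length-2 range for base means.
#' @param dispersion NB dispersion alpha (> 0); variance = mu + alpha mu^2.
#' @param library_size_factors Optional positive per-sample factors; default
#'   drawn log-normal(0, 0.1).
#' @param seed Integer seed; defaults to the design seed.
#' @param feature_prefix Prefix for generated feature ids.
#' @return List with `counts` (integer matrix), `samples` (sample sheet),
#'   `truth` (data.table feature_id, pattern, base_mean), and
#'   `library_size_factors`.
#' @export
simulate_counts <- function(design, templates = pattern_templates(),
                            n_per_template,
                            base_mean_range = c(50, 500),
                            dispersion = 0.05,
                            library_size_factors = NULL,
                            seed = design$seed,
                            feature_prefix = "gene") {
  stopifnot(inherits(design, "study_design"))
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("dispersion must be > 0")
  if (any(n_per_template < 0)) stop("n_per_template values must be >= 0")
  if (length(base_mean_range) != 2 || any(base_mean_range <= 0))
    stop("base_mean_range must be two positive values")
  check_templates(templates, length(design$conditions))
  if (is.null(names(n_per_template)) ||
      !all(names(n_per_template) %in% names(templates)))
    stop("n_per_template must be named by template label")

  samples <- design_samples(design)
  n_samp <- nrow(samples)
  set.seed(seed)
  if (is.null(library_size_factors)) {
    library_size_factors <- exp(stats::rnorm(n_samp, 0, 0.1))
  }
  if (length(library_size_factors) != n_samp || any(library_size_factors <= 0))
    stop("library_size_factors must be positive, one per sample")

  labels <- rep(names(n_per_template), times = n_per_template)
  n_feat <- length(labels)
  if (n_feat == 0) stop("no features requested")
  feature_id <- sprintf("%s_%05d", feature_prefix, seq_len(n_feat))
  base_mean <- exp(stats::runif(n_feat, log(base_mean_range[1]),
                                log(base_mean_range[2])))
  if (any(base_mean <= 0)) stop("base means must be positive")

  mult <- do.call(rbind, templates[labels])              # n_feat x n_cond
  cond_idx <- match(samples$condition, design$conditions)
  mu <- (base_mean * mult)[, cond_idx, drop = FALSE] *
    rep(library_size_factors, each = n_feat)
  size <- 1 / dispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
                   nrow = n_feat,
                   dimnames = list(feature_id, samples$sample_id))
  storage.mode(counts) <- "integer"

  list(counts = counts,
       samples = samples,
       truth = data.table::data.table(feature_id = feature_id,
                                      pattern = labels,
                                      base_mean = base_mean),
       library_size_factors = stats::setNames(library_size_factors,
                                              samples$sample_id))
}

#' Simulate a gene annotation along one synthetic contig
#'
#' Genes are laid out with roughly even TSS spacing (plus jitter) along a
#' single contig; coordinates are 0-based half-open throughout.
#'
#' @param n_genes Number of genes.
#' @param contig Contig name.
#' @param contig_length Contig length in bp.
#' @param seed Integer seed.
#' @return data.table gene_id, chrom, tss, strand, length_bp.
#' @export
simulate_gene_annotation <- function(n_genes, contig = "chrS",
                                     contig_length = 1e7, seed = 17L) {
  set.seed(seed)
  spacing <- contig_length / (n_genes + 1)
  if (spacing < 2000)
    stop("contig too small to place ", n_genes, " genes")
  jitter <- stats::runif(n_genes, -0.2, 0.2) * spacing
  tss <- as.integer(round(spacing * seq_len(n_genes) + jitter))
  tss <- pmin(pmax(tss, 1000L), as.integer(contig_length - 1000))
  data.table::data.table(
    gene_id = sprintf("gene_%05d", seq_len(n_genes)),
    chrom = contig,
    tss = tss,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    length_bp = as.integer(round(stats::runif(n_genes, 800, 5000)))
  )
}

#' Simulate per-condition cut-count tracks with motif footprints
#'
#' Within +/- `half_width` bp of each motif occurrence center the expected
#' per-base cut count is `flank_rate`, reduced to
#' `flank_rate * interior_fraction[motif, condition]` inside the motif
#' interval (the footprint). Outside these windows the track is zero. With
#' `noise = FALSE` the track equals its expectation exactly; with noise on,
#' per-base counts are Poisson.
#'
#' @param design A `study_design`.
#' @param motifs data.table chrom, start, end, motif_id, strand of occurrences;
#'   occurrences of one motif must not overlap.
#' @param flank_rate Expected per-base cuts in the flank (> 0).
#' @param interior_fraction Either a single value in (0, 1], a named vector
#'   per condition, or a motif x condition matrix (rownames = motif ids).
#' @param noise Draw Poisson noise around the expectation.
#' @param half_width Flanking window half-width (bp).
#' @param contig_length Contig length for bounds checking.
#' @param seed Integer seed.
#' @return List with `tracks` (named list of signal tracks, one per condition)
#'   and `truth_fpd` (motif x condition matrix of planted footprint depths,
#'   -log2 interior_fraction).
#' @export
simulate_cut_profiles <- function(design, motifs, flank_rate = 8,
                                  interior_fraction = 0.25,
                                  noise = TRUE, half_width = 200L,
                                  contig_length = 1e7,
                                  seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  if (flank_rate <= 0) stop("flank_rate must be positive")
  motifs <- data.table::as.data.table(motifs)
  if (any(motifs$end - motifs$start > 2L * half_width))
    stop("motif wider than its flanking window")
  if (any(motifs$start < half_width) ||
      any(motifs$end + half_width > contig_length))
    stop("motif window extends beyond the contig")

  motif_ids <- unique(motifs$motif_id)
  n_cond <- length(design$conditions)
  frac <- interior_fraction
  if (is.matrix(frac)) {
    if (!all(motif_ids %in% rownames(frac)) || ncol(frac) != n_cond)
      stop("interior_fraction matrix must cover all motifs x conditions")
    frac <- frac[motif_ids, , drop = FALSE]
  } else if (length(frac) == 1L) {
    frac <- matrix(frac, length(motif_ids), n_cond,
                   dimnames = list(motif_ids, design$conditions))
  } else if (length(frac) == n_cond) {
    frac <- matrix(rep(frac, each = length(motif_ids)), length(motif_ids),
                   n_cond, dimnames = list(motif_ids, design$conditions))
  } else stop("interior_fraction must be scalar, per-condition, or a matrix")
  colnames(frac) <- design$conditions
  if (any(frac <= 0) || any(frac > 1))
    stop("interior_fraction must lie in (0, 1]")

  contig <- motifs$chrom[1]
  if (!all(motifs$chrom == contig))
    stop("all motif occurrences must lie on one contig")

  # per-base expectation over the union of windows, built once per condition
  win_start <- pmax(0L, as.integer(motifs$start) - half_width)
  win_end <- pmin(as.integer(contig_length), as.integer(motifs$end) + half_width)
  cover <- IRanges::reduce(IRanges::IRanges(win_start + 1L, win_end))
  base_pos <- unlist(lapply(seq_along(cover), function(i)
    seq.int(IRanges::start(cover)[i], IRanges::end(cover)[i])), use.names = FALSE)
  # base_pos is 1-based inclusive; base b covers [b-1, b) in 0-based half-open
  set.seed(seed)
  tracks <- vector("list", n_cond)
  names(tracks) <- design$conditions
  for (ci in seq_len(n_cond)) {
    expect <- numeric(length(base_pos))
    in_window <- rep(FALSE, length(base_pos))
    for (k in seq_len(nrow(motifs))) {
      idx <- base_pos > win_start[k] & base_pos <= win_end[k]
      in_window <- in_window | idx
      expect[idx] <- expect[idx] + flank_rate
      interior <- base_pos > motifs$start[k] & base_pos <= motifs$end[k]
      f <- frac[motifs$motif_id[k], ci]
      expect[idx & interior] <- expect[idx & interior] -
        flank_rate * (1 - f)
    }
    value <- if (noise) stats::rpois(length(expect), expect) else expect
    tracks[[ci]] <- signal_track(data.table::data.table(
      chrom = contig, start = base_pos - 1L, end = base_pos,
      value = as.numeric(value))[value != 0],
      contigs = stats::setNames(as.integer(contig_length), contig))
  }
  list(tracks = tracks, truth_fpd = -log2(frac))
}

#' Simulate enhancer peaks linked to genes by nearest-TSS
#'
#' Plants, for a chosen fraction of pattern-E (overshoot) genes, a proximal
#' peak whose nearest TSS is the target gene and whose counts follow the
#' gene's kinetic template; remaining peaks are background (flat template)
#' placed midway between genes. The planted linkage is verified against
#' [nearest_gene()] at generation time.
#'
#' @param design A `study_design`.
#' @param annotation Gene annotation (see [simulate_gene_annotation()]).
#' @param gene_truth Truth table from [simulate_counts()] (feature_id, pattern).
#' @param linkage_fraction Fraction of pattern-E genes given a linked peak
#'   (planted count = floor(fraction * n)).
#' @param n_background Number of background peaks.
#' @param peak_width Peak width (bp).
#' @param templates,dispersion,base_mean_range,seed Passed to the count
#'   simulation for peaks.
#' @return List with `peaks` (data.table peak_id, chrom, start, end),
#'   `counts`, `samples`, `truth` (per-peak pattern), and `truth_linkage`
#'   (data.table peak_id, gene_id for planted links).
#' @export
simulate_enhancer_peaks <- function(design, annotation, gene_truth,
                                    linkage_fraction = 1.0,
                                    n_background = 200L,
                                    peak_width = 400L,
                                    templates = pattern_templates(),
                                    dispersion = 0.05,
                                    base_mean_range = c(50, 500),
                                    seed = design$seed) {
  if (linkage_fraction < 0 || linkage_fraction > 1)
    stop("linkage_fraction must lie in [0, 1]")
  ann <- data.table::as.data.table(annotation)
  data.table::setorder(ann, tss)
  e_genes <- gene_truth$feature_id[gene_truth$pattern == "E"]
  e_genes <- intersect(e_genes, ann$gene_id)
  n_linked <- floor(linkage_fraction * length(e_genes))
  set.seed(seed)
  linked_genes <- if (n_linked > 0) sort(sample(e_genes, n_linked)) else character()

  # safe placement radius: half the gap to the closest neighbouring TSS
  gap_prev <- c(Inf, diff(ann$tss))
  gap_next <- c(diff(ann$tss), Inf)
  safe <- pmin(gap_prev, gap_next) / 2 - peak_width
  names(safe) <- ann$gene_id

  peak_rows <- list()
  truth_link <- list()
  for (g in linked_genes) {
    i <- match(g, ann$gene_id)
    radius <- safe[[g]]
    if (is.infinite(radius)) radius <- 5000
    if (radius < peak_width)
      stop("contig too small to place a linked peak near ", g)
    offset <- round(stats::runif(1, peak_width, min(radius, 10000)))
    sign <- sample(c(-1L, 1L), 1L)
    center <- ann$tss[i] + sign * offset
    peak_rows[[length(peak_rows) + 1L]] <- data.table::data.table(
      chrom = ann$chrom[i],
      start = as.integer(center - peak_width / 2),
      end = as.integer(center + peak_width / 2),
      pattern = "E", gene_id = g)
  }
  # background peaks midway between adjacent genes (never nearest-tied)
  if (n_background > 0) {
    mids <- floor((ann$tss[-1] + ann$tss[-nrow(ann)]) / 2)
    if (length(mids) < 1) stop("need >= 2 genes for background peaks")
    sel <- sample(length(mids), n_background, replace = n_background > length(mids))
    for (m in mids[sel]) {
      peak_rows[[length(peak_rows) + 1L]] <- data.table::data.table(
        chrom = ann$chrom[1],
        start = as.integer(m - peak_width / 2),
        end = as.integer(m + peak_width / 2),
        pattern = "flat", gene_id = NA_character_)
    }
  }
  peaks <- data.table::rbindlist(peak_rows)
  peaks[, peak_id := sprintf("peak_%05d", seq_len(.N))]

  cnt <- simulate_counts(design, templates = templates,
                         n_per_template = table_to_named(table(peaks$pattern)),
                         base_mean_range = base_mean_range,
                         dispersion = dispersion,
                         seed = seed + 1L, feature_prefix = "tmp")
  # rows of cnt$counts are grouped by template label; map back to peak order
  counts <- cnt$counts
  idx_by_label <- split(seq_len(nrow(peaks)), peaks$pattern)
  new_rownames <- character(nrow(peaks))
  pos <- 1L
  for (lab in names(table_to_named(table(peaks$pattern)))) {
    ids <- idx_by_label[[lab]]
    new_rownames[pos:(pos + length(ids) - 1L)] <- peaks$peak_id[ids]
    pos <- pos + length(ids)
  }
  rownames(counts) <- new_rownames
  counts <- counts[peaks$peak_id, , drop = FALSE]

  truth_linkage <- peaks[!is.na(gene_id), .(peak_id, gene_id)]
  # internal consistency: every planted peak's nearest TSS is its target
  if (nrow(truth_linkage) > 0) {
    links <- nearest_gene(peaks[peaks$peak_id %in% truth_linkage$peak_id],
                          ann)
    chk <- merge(truth_linkage, links[, .(peak_id, gene_id_obs = gene_id)],
                 by = "peak_id")
    if (!all(chk$gene_id == chk$gene_id_obs))
      stop("contig too small: planted peak not nearest to its target gene")
  }
  list(peaks = peaks[, .(peak_id, chrom, start, end)],
       counts = counts,
       samples = cnt$samples,
       truth = peaks[, .(peak_id, pattern, gene_id)],
       truth_linkage = truth_linkage)
}

table_to_named <- function(tb) {
  stats::setNames(as.integer(tb), names(tb))
}

#' Simulate motif occurrences inside accessible sites
#'
#' Each site carries at most one motif occurrence (with probability
#' `prob_present`, motif identity uniform over `motif_ids`), placed with a
#' small jitter around the site center. One motif per site keeps the
#' flanking windows of different motifs from overlapping, so each motif's
#' aggregate footprint is attributable to that motif alone.
#'
#' @param sites data.table chrom, start, end (accessible sites).
#' @param motif_ids Character vector of motif names.
#' @param prob_present Probability that a site carries a motif.
#' @param width Motif width (bp).
#' @param seed Integer seed.
#' @return data.table chrom, start, end, motif_id, strand.
#' @export
simulate_motif_occurrences <- function(sites, motif_ids, prob_present = 0.8,
                                       width = 12L, seed = 17L) {
  sites <- data.table::as.data.table(sites)
  set.seed(seed)
  centers <- floor((sites$start + sites$end) / 2)
  keep <- stats::runif(nrow(sites)) < prob_present
  n <- sum(keep)
  if (n == 0) return(data.table::data.table())
  off <- as.integer(round(stats::runif(n, -20, 20)))
  st <- as.integer(centers[keep] + off - floor(width / 2))
  data.table::data.table(
    chrom = sites$chrom[keep], start = st, end = st + as.integer(width),
    motif_id = sample(motif_ids, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Simulate a complete fasting-refeeding dataset with planted truth
#'
#' Bundles gene counts, annotation, enhancer peaks, motif occurrences and
#' cut-count tracks into one coherent synthetic dataset on a single contig.
#'
#' @param design A `study_design`.
#' @param n_per_template Features per kinetic template (genes).
#' @param linkage_fraction Fraction of pattern-E genes with a linked peak.
#' @param n_background_peaks Background (flat) peaks.
#' @param motif_ids Motif names for the footprinting layer; the first motif
#'   is planted with condition-dependent footprint deepening (deeper in
#'   Refed_24h than Adlib).
#' @param dispersion,base_mean_range Passed to [simulate_counts()].
#' @param hard_mode Halve planted effect sizes.
#' @param seed Integer seed.
#' @return A list (class `refeed_dataset`) with all simulated layers and
#'   their truth labels.
#' @export
simulate_refeeding_dataset <- function(design = study_design(),
                                       n_per_template = c(A = 200, B = 200,
                                                          C = 100, D = 200,
                                                          E = 200, F = 200,
                                                          G = 200, flat = 2000),
                                       linkage_fraction = 0.6,
                                       n_background_peaks = 400L,
                                       motif_ids = sprintf("motif_%02d", 1:20),
                                       dispersion = 0.05,
                                       base_mean_range = c(50, 500),
                                       hard_mode = FALSE,
                                       seed = design$seed) {
  templates <- pattern_templates(hard_mode = hard_mode)
  genes <- simulate_counts(design, templates, n_per_template,
                           base_mean_range = base_mean_range,
                           dispersion = dispersion, seed = seed)
  annotation <- simulate_gene_annotation(nrow(genes$counts), seed = seed + 1L)
  annotation$gene_id <- genes$truth$feature_id
  enh <- simulate_enhancer_peaks(design, annotation, genes$truth,
                                 linkage_fraction = linkage_fraction,
                                 n_background = n_background_peaks,
                                 templates = templates,
                                 dispersion = dispersion,
                                 base_mean_range = base_mean_range,
                                 seed = seed + 2L)
  motifs <- simulate_motif_occurrences(enh$peaks, motif_ids,
                                       prob_present = 0.3, seed = seed + 3L)
  # motif 1 footprint deepens upon refeeding; the rest are static
  frac <- matrix(0.5, length(motif_ids), length(design$conditions),
                 dimnames = list(motif_ids, design$conditions))
  frac[1, ] <- c(0.5, 0.6, 0.5, 0.3, 0.25)
  cuts <- simulate_cut_profiles(design, motifs, flank_rate = 8,
                                interior_fraction = frac, noise = TRUE,
                                seed = seed + 4L)
  structure(list(design = design,
                 gene_counts = genes$counts,
                 samples = genes$samples,
                 gene_truth = genes$truth,
                 library_size_factors = genes$library_size_factors,
                 annotation = annotation,
                 peaks = enh$peaks,
                 peak_counts = enh$counts,
                 peak_truth = enh$truth,
                 truth_linkage = enh$truth_linkage,
                 motifs = motifs,
                 cut_tracks = cuts$tracks,
                 truth_fpd = cuts$truth_fpd,
                 seed = seed),
            class = "refeed_dataset")
}
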
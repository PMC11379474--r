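#' Classify enhancer kinetic and LXR-dependence patterns
#'
#' Applies the gene cutoffs to peak regulation calls:
#' * overshoot: repressed in Fasted vs Adlib AND induced in Refed_24h vs
#'   Adlib (accessibility exceeds the ad libitum level after refeeding).
#' * recovered: repressed in Fasted vs Adlib AND repressed in Fasted vs
#'   Refed_24h AND not induced in Refed_24h vs Adlib.
#' * refeeding-activated: induced in Refed_24h vs Adlib (a superset of
#'   overshoot).
#' * lxr_increased / lxr_decreased: induced / repressed in WT vs DKO (only
#'   when that contrast is supplied).
#'
#' @param calls data.table peak_id/feature_id, contrast, status with
#'   contrasts Fasted_vs_Adlib, Refed_24h_vs_Adlib, Fasted_vs_Refed_24h and
#'   optionally WT_vs_DKO.
#' @return data.table: peak_id, kinetic_pattern (overshoot / recovered /
#'   none), refeeding_activated (logical), and lxr_status when available.
#' @export
classify_enhancers <- function(calls) {
  if (!is.null(calls$peak_id) && is.null(calls$feature_id))
    data.table::setnames(calls <- data.table::copy(calls), "peak_id",
                         "feature_id")
  need <- c("Fasted_vs_Adlib", "Refed_24h_vs_Adlib", "Fasted_vs_Refed_24h")
  missing <- setdiff(need, unique(calls$contrast))
  if (length(missing) > 0)
    stop("missing contrast(s): ", paste(missing, collapse = ", "))
  ids <- sort(unique(calls$feature_id))
  fa <- contrast_status(calls, "Fasted_vs_Adlib", ids)
  ra <- contrast_status(calls, "Refed_24h_vs_Adlib", ids)
  fr <- contrast_status(calls, "Fasted_vs_Refed_24h", ids)

  pattern <- rep("none", length(ids))
  pattern[fa == "repressed" & fr == "repressed" & ra != "induced"] <- "recovered"
  pattern[fa == "repressed" & ra == "induced"] <- "overshoot"
  out <- data.table::data.table(peak_id = ids,
                                kinetic_pattern = pattern,
                                refeeding_activated = ra == "induced")
  if ("WT_vs_DKO" %in% calls$contrast) {
    wd <- contrast_status(calls, "WT_vs_DKO", ids)
    out[, lxr_status := data.table::fcase(wd == "induced", "increased",
                                          wd == "repressed", "decreased",
                                          default = "unchanged")]
  }
  out[]
}

#' Map each peak to its nearest gene by TSS distance
#'
#' Per peak, the gene minimizing |peak center - TSS| on the peak's contig.
#' Ties (equal distance, including duplicated TSS) are broken by the
#' lexicographically smaller gene id. The reported distance is signed in
#' transcription orientation: negative = peak upstream of the TSS.
#'
#' @param peaks data.table peak_id, chrom, start, end.
#' @param annotation Gene annotation: gene_id, chrom, tss, strand.
#' @return data.table peak_id, gene_id (NA when the contig carries no gene),
#'   distance (signed bp, NA when unassigned).
#' @export
nearest_gene <- function(peaks, annotation) {
  peaks <- data.table::as.data.table(peaks)
  ann <- data.table::as.data.table(annotation)
  centers <- site_centers(peaks)
  gene_out <- rep(NA_character_, nrow(peaks))
  dist_out <- rep(NA_real_, nrow(peaks))
  for (cc in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == cc)
    g <- ann[ann$chrom == cc]
    if (nrow(g) == 0) next
    data.table::setorder(g, tss, gene_id)
    # one entry per distinct TSS, carrying the lexicographically smallest id
    gu <- g[, .(gene_id = gene_id[1], strand = strand[1]), by = tss]
    tss <- gu$tss
    for (p in pi) {
      ctr <- centers[p]
      k <- findInterval(ctr, tss)
      cand <- unique(pmin(pmax(c(k, k + 1L), 1L), length(tss)))
      d <- abs(ctr - tss[cand])
      best <- cand[d == min(d)]
      if (length(best) > 1) {
        ids <- gu$gene_id[best]
        best <- best[order(ids)][1]
      }
      gene_out[p] <- gu$gene_id[best]
      signed <- ctr - tss[best]
      if (gu$strand[best] == "-") signed <- -signed
      dist_out[p] <- signed
    }
  }
  if (anyNA(gene_out))
    message(sum(is.na(gene_out)), " peak(s) on contigs without genes left unassigned")
  data.table::data.table(peak_id = peaks$peak_id, gene_id = gene_out,
                         distance = dist_out)
}

#' Fraction of a gene set with a proximal enhancer of a class
#'
#' "Proximal" means the gene is the nearest gene of at least one peak in the
#' class (optionally within `max_distance` bp).
#'
#' @param gene_set Character vector of gene ids (non-empty).
#' @param class_peaks Peak ids belonging to the enhancer class.
#' @param links Nearest-gene table from [nearest_gene()].
#' @param max_distance Optional cap on |distance| (default none).
#' @return List: n_genes, n_with_enhancer, fraction.
#' @export
proximal_enhancer_fraction <- function(gene_set, class_peaks, links,
                                       max_distance = Inf) {
  if (length(gene_set) == 0) stop("gene set must be non-empty")
  sub <- links[links$peak_id %in% class_peaks & !is.na(links$gene_id) &
                 abs(links$distance) <= max_distance]
  hit <- unique(sub$gene_id)
  n_with <- sum(gene_set %in% hit)
  list(n_genes = length(gene_set), n_with_enhancer = n_with,
       fraction = n_with / length(gene_set))
}

#' Compare proximal-enhancer fractions between two gene sets
#'
#' Two-sided Fisher exact test on the 2x2 table
#' (has / has-not proximal enhancer) x (set A / set B).
#'
#' @param set_a,set_b Gene id vectors.
#' @param class_peaks,links,max_distance As in
#'   [proximal_enhancer_fraction()].
#' @return List: fraction_a, fraction_b, table (2x2 matrix), p_value.
#' @export
compare_proximal_fractions <- function(set_a, set_b, class_peaks, links,
                                       max_distance = Inf) {
  fa <- proximal_enhancer_fraction(set_a, class_peaks, links, max_distance)
  fb <- proximal_enhancer_fraction(set_b, class_peaks, links, max_distance)
  tab <- matrix(c(fa$n_with_enhancer, fa$n_genes - fa$n_with_enhancer,
                  fb$n_with_enhancer, fb$n_genes - fb$n_with_enhancer),
                nrow = 2,
                dimnames = list(c("with", "without"), c("set_a", "set_b")))
  list(fraction_a = fa$fraction, fraction_b = fb$fraction, table = tab,
       p_value = stats::fisher.test(tab)$p.value)
}

#' Regulation-status breakdown of a gene group
#'
#' Counts and fractions of induced / repressed / unchanged genes in a group
#' under one contrast (e.g. WT vs DKO).
#'
#' @param group Character vector of gene ids (non-empty).
#' @param calls Regulation calls (feature_id, status) for the contrast.
#' @return data.table status, n, fraction. Groups with no tested gene return
#'   zero counts with a warning.
#' @export
group_regulation_breakdown <- function(group, calls) {
  if (length(group) == 0) stop("group must be non-empty")
  st <- calls$status[match(group, calls$feature_id)]
  tested <- st[!is.na(st)]
  statuses <- c("induced", "repressed", "unchanged")
  n <- vapply(statuses, function(s) sum(tested == s), 0L)
  if (length(tested) == 0) {
    warning("no tested genes in group")
    frac <- rep(0, 3)
  } else frac <- n / length(tested)
  data.table::data.table(status = statuses, n = n, fraction = frac)
}

#' Windowed occupancy at enhancer classes
#'
#' Runs [window_signal()] on each class of sites plus an "all_sites"
#' baseline, and compares per-site occupancy between every class and the
#' baseline (and between classes) with two-sided Mann-Whitney U tests.
#'
#' @param track A `signal_track` (e.g. ChIP signal).
#' @param classes Named list of site tables (chrom, start, end).
#' @param baseline Optional baseline site table (e.g. all accessible sites).
#' @param half_width Window half-width (default 200).
#' @return List: `summary` (data.table class, n_sites, mean, p10, p90),
#'   `per_site` (named list of per-site tables), `tests` (data.table
#'   class_a, class_b, p_value).
#' @export
occupancy_at_classes <- function(track, classes, baseline = NULL,
                                 half_width = 200L) {
  if (length(classes) == 0 || any(!vapply(classes, nrow, 0) > 0))
    stop("classes must be non-empty site tables")
  if (!is.null(baseline)) classes <- c(classes, list(all_sites = baseline))
  per_site <- lapply(classes, function(s)
    window_signal(track, s, half_width)$per_site)
  summary <- data.table::rbindlist(lapply(names(classes), function(nm) {
    x <- per_site[[nm]]$count
    qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
    data.table::data.table(class = nm, n_sites = length(x), mean = mean(x),
                           p10 = qs[1], p90 = qs[2])
  }))
  nms <- names(classes)
  tests <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i >= j) next
    p <- stats::wilcox.test(per_site[[nms[i]]]$count,
                            per_site[[nms[j]]]$count,
                            alternative = "two.sided", exact = FALSE)$p.value
    tests[[length(tests) + 1L]] <- data.table::data.table(
      class_a = nms[i], class_b = nms[j], p_value = p)
  }
  list(summary = summary, per_site = per_site,
       tests = data.table::rbindlist(tests))
}
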
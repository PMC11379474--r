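#' Construct a signal track
#'
#' A sparse per-base signal (bedGraph-style runs) over named contigs.
#' Coordinates are 0-based half-open.
#'
#' @param intervals data.table/data.frame with chrom, start, end, value.
#' @param contigs Named integer vector of contig lengths.
#' @param scaled Internal: scale factor already applied.
#' @return Object of class `signal_track`.
#' @export
signal_track <- function(intervals, contigs, scaled = NA_real_) {
  iv <- data.table::as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(iv)))
  if (nrow(iv) > 0) {
    if (any(iv$start >= iv$end)) stop("intervals must satisfy start < end")
    if (any(iv$value < 0)) stop("signal values must be >= 0")
    unknown <- setdiff(unique(iv$chrom), names(contigs))
    if (length(unknown) > 0)
      stop("interval on unknown contig: ", paste(unknown, collapse = ", "))
  }
  data.table::setorder(iv, chrom, start)
  structure(list(intervals = iv, contigs = contigs, scaled = scaled),
            class = "signal_track")
}

#' Total signal of a track
#'
#' @param track A `signal_track`.
#' @return Sum of value x width over all runs.
#' @export
track_total <- function(track) {
  iv <- track$intervals
  if (nrow(iv) == 0) return(0)
  sum(iv$value * (iv$end - iv$start))
}

#' Scale a track to a fixed total of 1e7
#'
#' Every value is multiplied by 1e7 / total, the library-normalization
#' convention for browser tracks. Applying the scaling twice is a no-op.
#'
#' @param track A `signal_track`.
#' @param target Target total (default 1e7).
#' @return Scaled `signal_track`.
#' @export
scale_track <- function(track, target = 1e7) {
  total <- track_total(track)
  if (total <= 0) stop("cannot scale an empty track")
  factor <- target / total
  iv <- data.table::copy(track$intervals)
  iv[, value := value * factor]
  signal_track(iv, track$contigs, scaled = factor)
}

site_centers <- function(sites) {
  as.integer(floor((sites$start + sites$end) / 2))
}

# overlap pairs between track runs and windows, as a data.table with the
# clipped run, the window index, and the window start (for offsets)
track_window_overlaps <- function(track, win) {
  iv <- track$intervals
  out <- list()
  for (cc in unique(win$chrom)) {
    ivc <- iv[iv$chrom == cc]
    winc_idx <- which(win$chrom == cc)
    if (nrow(ivc) == 0 || length(winc_idx) == 0) next
    q <- IRanges::IRanges(ivc$start + 1L, ivc$end)
    s <- IRanges::IRanges(win$start[winc_idx] + 1L, win$end[winc_idx])
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    out[[cc]] <- data.table::data.table(
      win_idx = winc_idx[si],
      start = pmax(ivc$start[qi], win$start[winc_idx[si]]),
      end = pmin(ivc$end[qi], win$end[winc_idx[si]]),
      value = ivc$value[qi])
  }
  data.table::rbindlist(out)
}

#' Windowed signal around site centers
#'
#' Sums track signal in the half-open window
#' `[center - half_width, center + half_width)` around each site center
#' (center = floor((start + end) / 2)). Windows clipped at a contig edge are
#' flagged. The summary reports the mean and the 10th/90th percentiles across
#' sites, the plotting convention for box plots.
#'
#' @param track A `signal_track`.
#' @param sites data.table chrom, start, end (and optionally a `site_id`).
#' @param half_width Window half-width in bp (default 200).
#' @return List: `per_site` (data.table site_id, count, clipped), `mean`,
#'   `p10`, `p90`.
#' @export
window_signal <- function(track, sites, half_width = 200L) {
  sites <- data.table::as.data.table(sites)
  if (nrow(sites) == 0) stop("sites must be non-empty")
  if (is.null(sites$site_id))
    sites$site_id <- sprintf("site_%05d", seq_len(nrow(sites)))
  centers <- site_centers(sites)
  clens <- track$contigs[sites$chrom]
  win <- data.table::data.table(chrom = sites$chrom,
                                start = centers - half_width,
                                end = centers + half_width)
  clipped <- win$start < 0 | (!is.na(clens) & win$end > clens)
  win[, start := pmax(start, 0L)]
  if (any(!is.na(clens))) win[, end := pmin(end, clens)]

  ov <- track_window_overlaps(track, win)
  counts <- numeric(nrow(sites))
  if (nrow(ov) > 0) {
    sums <- ov[, .(count = sum(value * (end - start))), by = win_idx]
    counts[sums$win_idx] <- sums$count
  }
  per_site <- data.table::data.table(site_id = sites$site_id,
                                     count = counts, clipped = clipped)
  qs <- stats::quantile(counts, c(0.1, 0.9), names = FALSE, type = 7)
  list(per_site = per_site, mean = mean(counts), p10 = qs[1], p90 = qs[2])
}

#' Binned aggregate signal profile around site centers
#'
#' Averages, over sites, the track signal in `bin`-bp bins across
#' `[center - half_width, center + half_width)`. The value of a bin is the
#' summed count within the bin averaged across sites (i.e. bin width times
#' the mean per-bp density; a uniform track of value v gives `bin * v` in
#' every bin). Sites are padded with zero where the window is empty.
#'
#' @param track A `signal_track`.
#' @param sites data.table chrom, start, end.
#' @param half_width Profile half-width in bp (default 4000).
#' @param bin Bin width in bp; must divide 2 * half_width (default 10).
#' @return data.table bin_offset (bp of bin start relative to center),
#'   mean_value (mean per-bp signal).
#' @export
aggregate_profile <- function(track, sites, half_width = 4000L, bin = 10L) {
  if ((2L * half_width) %% bin != 0) stop("bin must divide 2 * half_width")
  sites <- data.table::as.data.table(sites)
  if (nrow(sites) == 0) stop("sites must be non-empty")
  centers <- site_centers(sites)
  win <- data.table::data.table(chrom = sites$chrom,
                                start = pmax(centers - half_width, 0L),
                                end = centers + half_width)
  clens <- track$contigs[sites$chrom]
  if (any(!is.na(clens))) win[, end := pmin(end, clens)]
  n_bins <- (2L * half_width) %/% bin
  ov <- track_window_overlaps(track, win)
  sums <- numeric(n_bins)
  if (nrow(ov) > 0) {
    # split clipped runs at bin boundaries in offset space, vectorized
    off_start <- ov$start - centers[ov$win_idx] + half_width   # in [0, 2hw)
    off_end <- ov$end - centers[ov$win_idx] + half_width
    n_pieces <- (off_end - 1L) %/% bin - off_start %/% bin + 1L
    row <- rep(seq_len(nrow(ov)), n_pieces)
    first_bin <- off_start %/% bin
    piece <- unlist(lapply(n_pieces, seq_len), use.names = FALSE) - 1L
    b <- first_bin[row] + piece                                # bin index
    lo <- pmax(off_start[row], b * bin)
    hi <- pmin(off_end[row], (b + 1L) * bin)
    contrib <- ov$value[row] * (hi - lo)
    agg <- rowsum(contrib, b)
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  data.table::data.table(
    bin_offset = seq.int(-half_width, half_width - bin, by = bin),
    mean_value = sums / nrow(sites))
}

#' Annotate sites as promoter-proximal or distal
#'
#' A site is promoter-proximal iff its center lies within
#' `[TSS - upstream, TSS + downstream]` of at least one gene, measured in
#' transcription orientation (so the window flips on minus-strand genes).
#' Genes with unknown strand are treated as plus strand (with a message).
#'
#' @param sites data.table chrom, start, end.
#' @param annotation Gene annotation: gene_id, chrom, tss, strand.
#' @param upstream,downstream Window bounds in bp (defaults 1000 / 100).
#' @return List: `per_site` (data.table site_id, class), `fraction_distal`.
#' @export
annotate_promoter_proximal <- function(sites, annotation,
                                       upstream = 1000L, downstream = 100L) {
  sites <- data.table::as.data.table(sites)
  ann <- data.table::as.data.table(annotation)
  if (is.null(sites$site_id))
    sites$site_id <- sprintf("site_%05d", seq_len(nrow(sites)))
  bad <- !ann$strand %in% c("+", "-")
  if (any(bad)) {
    message(sum(bad), " gene(s) with unknown strand treated as '+'")
    ann$strand[bad] <- "+"
  }
  win_lo <- ifelse(ann$strand == "+", ann$tss - upstream,
                   ann$tss - downstream)
  win_hi <- ifelse(ann$strand == "+", ann$tss + downstream,
                   ann$tss + upstream)
  centers <- site_centers(sites)
  proximal <- rep(FALSE, nrow(sites))
  for (cc in unique(sites$chrom)) {
    gi <- which(ann$chrom == cc)
    si <- which(sites$chrom == cc)
    if (length(gi) == 0 || length(si) == 0) next
    q <- IRanges::IRanges(centers[si] + 1L, centers[si] + 1L)
    s <- IRanges::IRanges(win_lo[gi] + 1L, win_hi[gi] + 1L)
    hits <- IRanges::findOverlaps(q, s)
    proximal[si[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  per_site <- data.table::data.table(
    site_id = sites$site_id,
    class = ifelse(proximal, "promoter-proximal", "distal"))
  list(per_site = per_site, fraction_distal = mean(!proximal))
}
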
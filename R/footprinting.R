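#' Aggregate cut-count profile around motif occurrences
#'
#' Pools per-base cut counts at offsets -200..+199 relative to occurrence
#' centers (center = floor((start + end) / 2)), over all occurrences lying
#' inside accessible sites. Minus-strand occurrences are reversed so offsets
#' are in motif orientation.
#'
#' @param track A `signal_track` of cut counts.
#' @param occurrences data.table chrom, start, end, motif_id, strand.
#' @param accessible_sites Optional site table; occurrences not overlapping
#'   any site are dropped before pooling.
#' @param motif_id Motif to profile (default: the single motif present).
#' @param half_width Profile half-width (default 200).
#' @return Object of class `motif_profile`: `motif_id`, `width` (bp),
#'   `counts` (numeric, names = offsets -half_width..half_width-1),
#'   `n_occurrences`.
#' @export
motif_cut_profile <- function(track, occurrences, accessible_sites = NULL,
                              motif_id = NULL, half_width = 200L) {
  occ <- data.table::as.data.table(occurrences)
  if (is.null(motif_id)) {
    motif_id <- unique(occ$motif_id)
    if (length(motif_id) != 1)
      stop("multiple motifs present; pass motif_id")
  }
  sel <- occ[["motif_id"]] == motif_id
  occ <- occ[which(sel), ]
  if (!is.null(accessible_sites)) {
    sites <- data.table::as.data.table(accessible_sites)
    keep <- rep(FALSE, nrow(occ))
    for (cc in unique(occ$chrom)) {
      oi <- which(occ$chrom == cc)
      si <- which(sites$chrom == cc)
      if (length(oi) == 0 || length(si) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(occ$start[oi] + 1L, occ$end[oi]),
        IRanges::IRanges(sites$start[si] + 1L, sites$end[si]))
      keep[oi[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    occ <- occ[keep]
  }
  if (nrow(occ) == 0)
    stop("no occurrences of ", motif_id, " inside accessible sites")
  width <- as.integer(round(stats::median(occ$end - occ$start)))

  centers <- site_centers(occ)
  win <- data.table::data.table(chrom = occ$chrom,
                                start = pmax(centers - half_width, 0L),
                                end = centers + half_width)
  clens <- track$contigs[occ$chrom]
  if (any(!is.na(clens))) win[, end := pmin(end, clens)]
  ov <- track_window_overlaps(track, win)
  counts <- numeric(2L * half_width)
  offsets <- seq.int(-half_width, half_width - 1L)
  if (nrow(ov) > 0) {
    # expand clipped runs to per-base contributions in offset space
    len <- ov$end - ov$start
    row <- rep(seq_len(nrow(ov)), len)
    pos <- ov$start[row] + sequence(len) - 1L     # 0-based base index
    rel <- pos - centers[ov$win_idx][row]         # genomic offset
    minus <- occ$strand[ov$win_idx][row] == "-"
    rel[minus] <- -rel[minus]                     # orientation flip
    ok <- rel >= -half_width & rel < half_width
    agg <- rowsum(ov$value[row][ok], rel[ok])
    counts[as.integer(rownames(agg)) + half_width + 1L] <- agg[, 1]
  }
  structure(list(motif_id = motif_id, width = width,
                 counts = stats::setNames(counts, offsets),
                 n_occurrences = nrow(occ)),
            class = "motif_profile")
}

#' Footprint depth and flanking accessibility of a motif profile
#'
#' With per-offset density d(o) = (counts(o) + pseudocount) / n_occurrences:
#' * FA = log2 mean density over the flank band 35 < |offset| <= 200;
#' * FPD = FA - log2 mean density over the motif interior, the offsets
#'   covered by the motif itself (-floor(w/2) .. ceiling(w/2) - 1 around the
#'   floor midpoint).
#'
#' A flat profile therefore has FPD = 0, and scaling all counts by c shifts
#' FA by log2 c while leaving FPD unchanged (up to the pseudocount).
#'
#' @param profile A `motif_profile`.
#' @param pseudocount Added to every offset count (default 0.5).
#' @param flank_inner,flank_outer Flank band bounds (default 35 / 200).
#' @return List: motif_id, fa, fpd, n_occurrences, width.
#' @export
footprint_stats <- function(profile, pseudocount = 0.5,
                            flank_inner = 35L, flank_outer = 200L) {
  stopifnot(inherits(profile, "motif_profile"))
  w <- profile$width
  if (w >= 2L * flank_inner)
    stop("motif width ", w, " >= ", 2L * flank_inner,
         ": interior does not fit inside the core exclusion zone")
  offsets <- as.integer(names(profile$counts))
  dens <- (profile$counts + pseudocount) / profile$n_occurrences
  interior <- offsets >= -floor(w / 2) & offsets <= ceiling(w / 2) - 1L
  flank <- abs(offsets) > flank_inner & abs(offsets) <= flank_outer
  fa <- log2(mean(dens[flank]))
  fpd <- fa - log2(mean(dens[interior]))
  list(motif_id = profile$motif_id, fa = fa, fpd = fpd,
       n_occurrences = profile$n_occurrences, width = w)
}

#' Footprint statistics for every motif in one condition
#'
#' @param track A `signal_track` of cut counts.
#' @param occurrences Motif occurrence table (chrom, start, end, motif_id,
#'   strand).
#' @param accessible_sites Optional accessible-site filter.
#' @param pseudocount Passed to [footprint_stats()].
#' @return data.table motif_id, fa, fpd, n_occurrences.
#' @export
footprint_stats_all <- function(track, occurrences, accessible_sites = NULL,
                                pseudocount = 0.5) {
  ids <- sort(unique(occurrences$motif_id))
  data.table::rbindlist(lapply(ids, function(m) {
    pr <- motif_cut_profile(track, occurrences, accessible_sites, m)
    st <- footprint_stats(pr, pseudocount)
    data.table::data.table(motif_id = m, fa = st$fa, fpd = st$fpd,
                           n_occurrences = st$n_occurrences)
  }))
}

#' Exact Tukey halfspace depth of each point in a 2-D cloud
#'
#' depth(p) = minimum, over all closed halfplanes containing p, of the number
#' of points (including p) in the halfplane; computed exactly by an angular
#' sweep per point.
#'
#' @param xy Two-column numeric matrix.
#' @return Integer vector of depths.
#' @export
tukey_depth <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  two_pi <- 2 * pi
  vapply(seq_len(n), function(i) {
    v <- sweep(xy, 2, xy[i, ])
    dup <- rowSums(abs(v)) == 0                  # includes the point itself
    a <- sort(atan2(v[!dup, 2], v[!dup, 1]) %% two_pi)
    m <- length(a)
    if (m == 0) return(n)
    # N(psi) = #{a_j in the closed arc [psi, psi + pi]} is piecewise constant
    # with breakpoints at a_j and a_j - pi; evaluate at every breakpoint and
    # at the midpoints of consecutive breakpoints, then take the minimum.
    br <- sort(unique(c(a, (a - pi) %% two_pi)))
    mids <- (br + diff(c(br, br[1] + two_pi)) / 2) %% two_pi
    cand <- c(br, mids)
    counts <- vapply(cand, function(psi) {
      d <- (a - psi) %% two_pi
      sum(d <= pi + 1e-12 | d >= two_pi - 1e-12)
    }, 0L)
    min(counts) + sum(dup)
  }, 0L)
}

point_in_convex_polygon <- function(pts, poly) {
  # poly: vertices in counterclockwise (chull) order; boundary counts inside
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(n)) {
    a <- poly[k, ]
    b <- poly[if (k == n) 1L else k + 1L, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
      (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cross >= -1e-12
  }
  inside
}

#' Bagplot of per-motif footprint deltas between two conditions
#'
#' Computes per-motif deltas (condition B minus A) of FA and FPD, Tukey
#' halfspace depths of the delta cloud, the bag (convex hull of the deepest
#' half of the points), the fence (bag inflated x3 about the depth median),
#' and the motifs outside the fence (outliers). Motifs in the jointly
#' increased quadrant (dFA > 0 and dFPD > 0) are reported separately.
#'
#' @param stats_a,stats_b data.tables from [footprint_stats_all()] for the
#'   two conditions (same motif universe).
#' @param fence_factor Fence inflation factor (default 3).
#' @return List of class `bagplot_result`: `deltas` (data.table motif_id,
#'   dfa, dfpd, depth, in_bag, outlier, jointly_increased), `bag` and
#'   `fence` (vertex matrices), `median` (depth median coordinates),
#'   `outliers` (motif ids).
#' @export
bagfoot_delta <- function(stats_a, stats_b, fence_factor = 3) {
  if (!setequal(stats_a$motif_id, stats_b$motif_id))
    stop("the two conditions must cover the same motif universe")
  m <- merge(stats_a[, .(motif_id, fa_a = fa, fpd_a = fpd)],
             stats_b[, .(motif_id, fa_b = fa, fpd_b = fpd)],
             by = "motif_id")
  if (nrow(m) < 10)
    stop("need >= 10 motifs for a stable depth computation")
  m[, dfa := fa_b - fa_a]
  m[, dfpd := fpd_b - fpd_a]
  xy <- cbind(m$dfa, m$dfpd)
  depth <- tukey_depth(xy)

  # bag: smallest depth region holding at least half the points
  dsort <- sort(unique(depth), decreasing = TRUE)
  d_star <- dsort[1]
  for (d in dsort) {
    if (sum(depth >= d) >= nrow(xy) / 2) { d_star <- d; break }
  }
  bag_pts <- xy[depth >= d_star, , drop = FALSE]
  hull <- grDevices::chull(bag_pts)
  bag <- bag_pts[rev(hull), , drop = FALSE]      # chull is clockwise; reverse
  med <- colMeans(xy[depth == max(depth), , drop = FALSE])
  fence <- sweep(sweep(bag, 2, med), 1, rep(fence_factor, nrow(bag)), "*")
  fence <- sweep(fence, 2, med, "+")
  inside <- point_in_convex_polygon(xy, fence)
  m[, depth := depth]
  m[, in_bag := depth >= d_star]
  m[, outlier := !inside]
  m[, jointly_increased := dfa > 0 & dfpd > 0]
  structure(list(deltas = m[], bag = bag, fence = fence, median = med,
                 outliers = m$motif_id[!inside]),
            class = "bagplot_result")
}

#' Known-motif enrichment with whole-landscape background
#'
#' For each motif, counts foreground and background sites containing at
#' least one occurrence and tests enrichment with a one-sided hypergeometric
#' test (foreground drawn from the background landscape), BH-adjusted across
#' motifs.
#'
#' @param foreground Site table (must be a subset of the background sites).
#' @param background Site table: all accessible sites.
#' @param occurrences Motif occurrence table.
#' @return data.table motif_id, fg_with, fg_total, bg_with, bg_total,
#'   fold_enrichment, p_value, padj.
#' @export
motif_enrichment <- function(foreground, background, occurrences) {
  fg <- data.table::as.data.table(foreground)
  bg <- data.table::as.data.table(background)
  key <- function(s) paste(s$chrom, s$start, s$end, sep = ":")
  if (!all(key(fg) %in% key(bg)))
    stop("foreground sites must be a subset of the background")
  occ <- data.table::as.data.table(occurrences)
  sites_with_motif <- function(sites, oc) {
    hit <- rep(FALSE, nrow(sites))
    for (cc in unique(sites$chrom)) {
      si <- which(sites$chrom == cc)
      oi <- which(oc$chrom == cc)
      if (length(si) == 0 || length(oi) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(sites$start[si] + 1L, sites$end[si]),
        IRanges::IRanges(oc$start[oi] + 1L, oc$end[oi]))
      hit[si[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    hit
  }
  ids <- sort(unique(occ$motif_id))
  out <- data.table::rbindlist(lapply(ids, function(mid) {
    oc <- occ[occ$motif_id == mid]
    k <- sum(sites_with_motif(fg, oc))
    kk <- sum(sites_with_motif(bg, oc))
    p <- stats::phyper(k - 1, kk, nrow(bg) - kk, nrow(fg),
                       lower.tail = FALSE)
    data.table::data.table(
      motif_id = mid, fg_with = k, fg_total = nrow(fg),
      bg_with = kk, bg_total = nrow(bg),
      fold_enrichment = (k / nrow(fg)) / max(kk / nrow(bg),
                                             .Machine$double.eps),
      p_value = p)
  }))
  out[, padj := stats::p.adjust(p_value, method = "BH")]
  out[]
}
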
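spike_track <- function(pos, value = 5, len = 100000L) {
  signal_track(
    data.table::data.table(chrom = "chrS", start = pos, end = pos + 1L,
                           value = value),
    contigs = c(chrS = len))
}

test_that("motif cut profiles are additive and strand-oriented", {
  # single occurrence with a spike at its center: only offset 0 is nonzero
  occ <- data.table::data.table(chrom = "chrS", start = 9995L, end = 10005L,
                                motif_id = "m1", strand = "+")
  pr <- motif_cut_profile(spike_track(10000L), occ)
  expect_equal(unname(pr$counts["0"]), 5)
  expect_equal(sum(pr$counts), 5)

  # two identical occurrences double the profile
  occ2 <- rbind(occ, data.table::data.table(chrom = "chrS", start = 19995L,
                                            end = 20005L, motif_id = "m1",
                                            strand = "+"))
  tr2 <- signal_track(rbind(spike_track(10000L)$intervals,
                            spike_track(20000L)$intervals),
                      contigs = c(chrS = 100000L))
  pr2 <- motif_cut_profile(tr2, occ2)
  expect_equal(unname(pr2$counts["0"]), 10)

  # minus-strand occurrence: genomic +5 appears at motif offset -5
  occ_minus <- data.table::data.table(chrom = "chrS", start = 9995L,
                                      end = 10005L, motif_id = "m1",
                                      strand = "-")
  pr3 <- motif_cut_profile(spike_track(10005L), occ_minus)
  expect_equal(unname(pr3$counts["-5"]), 5)
  expect_equal(sum(pr3$counts), 5)

  # occurrences outside accessible sites are excluded
  sites <- data.table::data.table(chrom = "chrS", start = 50000L,
                                  end = 50400L)
  expect_error(motif_cut_profile(spike_track(10000L), occ, sites), "m1")
})

test_that("footprint statistics match their closed forms", {
  d <- study_design(conditions = "A", replicates = 2L)
  motifs <- data.table::data.table(
    chrom = "chrS", start = seq(5000L, 65000L, by = 1000L))
  motifs[, end := start + 12L]
  motifs[, motif_id := "m1"]
  motifs[, strand := "+"]

  # flat profile: FPD exactly 0
  flat <- simulate_cut_profiles(d, motifs, flank_rate = 8,
                                interior_fraction = 1, noise = FALSE,
                                seed = 1)
  st_flat <- footprint_stats(motif_cut_profile(flat$tracks$A, motifs))
  expect_equal(st_flat$fpd, 0)

  # interior density one quarter of the flank: FPD = 2 within 0.05
  fp <- simulate_cut_profiles(d, motifs, flank_rate = 8,
                              interior_fraction = 0.25, noise = FALSE,
                              seed = 1)
  st <- footprint_stats(motif_cut_profile(fp$tracks$A, motifs))
  expect_lt(abs(st$fpd - 2), 0.05)

  # doubling the track: FA rises by 1, FPD unchanged
  iv <- data.table::copy(fp$tracks$A$intervals)
  iv[, value := value * 2]
  st2 <- footprint_stats(motif_cut_profile(
    signal_track(iv, fp$tracks$A$contigs), motifs))
  expect_lt(abs((st2$fa - st$fa) - 1), 0.01)
  expect_lt(abs(st2$fpd - st$fpd), 0.01)

  # a motif too wide for the core exclusion zone is refused
  wide <- data.table::copy(motifs)[, end := start + 80L]
  pr_wide <- motif_cut_profile(fp$tracks$A, wide)
  expect_error(footprint_stats(pr_wide), "width")
})

test_that("exact Tukey depth matches brute-force enumeration", {
  set.seed(61)
  xy <- cbind(rnorm(25), rnorm(25))
  expect_identical(tukey_depth(xy), as.integer(brute_force_depth(xy)))

  # collinear-with-duplicates corner case
  xy2 <- rbind(c(0, 0), c(1, 0), c(2, 0), c(1, 0), c(1, 1))
  expect_identical(tukey_depth(xy2), as.integer(brute_force_depth(xy2)))
})

test_that("the bagplot flags a planted far outlier and only that one", {
  set.seed(62)
  n <- 200
  base <- data.table::data.table(
    motif_id = sprintf("m%03d", 1:n),
    fa = rnorm(n, 5, 0.1), fpd = rnorm(n, 1, 0.1),
    n_occurrences = 100L)
  delta <- data.table::data.table(
    motif_id = base$motif_id,
    fa = base$fa + rnorm(n, 0, 0.05),
    fpd = base$fpd + rnorm(n, 0, 0.05),
    n_occurrences = 100L)
  # one motif moves 10 SD in both axes
  delta[motif_id == "m001", `:=`(fa = fa + 0.5, fpd = fpd + 0.5)]
  bag <- bagfoot_delta(base, delta)
  expect_true("m001" %in% bag$outliers)
  expect_true(bag$deltas[motif_id == "m001"]$jointly_increased)
  # the planted motif is the most extreme point of the delta cloud
  dd <- bag$deltas
  r <- sqrt((dd$dfa - median(dd$dfa))^2 + (dd$dfpd - median(dd$dfpd))^2)
  expect_equal(dd$motif_id[which.max(r)], "m001")

  # identical conditions: all deltas zero, no outliers
  same <- bagfoot_delta(base, base)
  expect_identical(same$outliers, character(0))
  expect_true(all(same$deltas$dfa == 0))

  expect_error(bagfoot_delta(base[1:5], delta[1:5]), "10 motifs")
  expect_error(bagfoot_delta(base, delta[1:100]), "universe")
})

test_that("adding a point at the depth median leaves the outlier set unchanged", {
  set.seed(63)
  n <- 80
  sa <- data.table::data.table(motif_id = sprintf("m%03d", 1:n),
                               fa = rnorm(n), fpd = rnorm(n),
                               n_occurrences = 50L)
  sb <- data.table::data.table(motif_id = sa$motif_id,
                               fa = sa$fa + rnorm(n, 0, 0.2),
                               fpd = sa$fpd + rnorm(n, 0, 0.2),
                               n_occurrences = 50L)
  bag <- bagfoot_delta(sa, sb)
  med <- bag$median
  sa2 <- rbind(sa, data.table::data.table(motif_id = "extra", fa = 0,
                                          fpd = 0, n_occurrences = 50L))
  sb2 <- rbind(sb, data.table::data.table(motif_id = "extra", fa = med[1],
                                          fpd = med[2], n_occurrences = 50L))
  bag2 <- bagfoot_delta(sa2, sb2)
  expect_setequal(setdiff(bag2$outliers, "extra"), bag$outliers)
})

test_that("FPD is invariant and FA shifts log2 c under track scaling", {
  d <- study_design(conditions = "A", replicates = 2L)
  motifs <- data.table::data.table(
    chrom = "chrS", start = seq(5000L, 45000L, by = 1000L))
  motifs[, end := start + 12L]
  motifs[, motif_id := "m1"]
  motifs[, strand := "+"]
  cp <- simulate_cut_profiles(d, motifs, flank_rate = 20,
                              interior_fraction = 0.5, noise = TRUE, seed = 2)
  st <- footprint_stats(motif_cut_profile(cp$tracks$A, motifs))
  for (c_mult in c(0.5, 4)) {
    iv <- data.table::copy(cp$tracks$A$intervals)
    iv[, value := value * c_mult]
    st_c <- footprint_stats(motif_cut_profile(
      signal_track(iv, cp$tracks$A$contigs), motifs))
    expect_lt(abs((st_c$fa - st$fa) - log2(c_mult)), 0.02)
    expect_lt(abs(st_c$fpd - st$fpd), 0.02)
  }
})

test_that("motif enrichment matches the hypergeometric tail and its edge cases", {
  sites <- data.table::data.table(
    chrom = "chrS", start = seq(1000L, by = 1000L, length.out = 50))
  sites[, end := start + 400L]
  centers <- floor((sites$start + sites$end) / 2)

  # motif in every site: fold 1, p 1
  occ_all <- data.table::data.table(chrom = "chrS", start = centers,
                                    end = centers + 10L, motif_id = "m1",
                                    strand = "+")
  res_all <- motif_enrichment(sites[1:20], sites, occ_all)
  expect_equal(res_all$fold_enrichment, 1)
  expect_equal(res_all$p_value, 1)

  # foreground = exactly the sites carrying the motif: maximal enrichment,
  # p equals the hypergeometric tail by direct summation
  occ_some <- occ_all[1:15]
  res <- motif_enrichment(sites[1:15], sites, occ_some)
  p_direct <- sum(sapply(15:15, function(k)
    choose(15, k) * choose(35, 15 - k) / choose(50, 15)))
  expect_equal(res$p_value, p_direct, tolerance = 1e-12)

  expect_error(motif_enrichment(
    data.table::data.table(chrom = "chrX", start = 1L, end = 10L),
    sites, occ_all), "subset")
})

test_that("a planted pattern-specific motif ranks first in nearly all simulations", {
  set.seed(64)
  hits <- replicate(100, {
    n_fg <- 40; n_bg_extra <- 160
    starts <- seq(1000L, by = 1000L, length.out = n_fg + n_bg_extra)
    sites <- data.table::data.table(chrom = "chrS", start = starts,
                                    end = starts + 400L)
    fg <- sites[1:n_fg]
    centers <- floor((sites$start + sites$end) / 2)
    present_planted <- c(runif(n_fg) < 0.8, runif(n_bg_extra) < 0.1)
    occ <- list(data.table::data.table(
      chrom = "chrS", start = centers[present_planted],
      end = centers[present_planted] + 10L,
      motif_id = "planted", strand = "+"))
    for (m in 1:5) {
      pres <- runif(n_fg + n_bg_extra) < 0.3
      occ[[m + 1]] <- data.table::data.table(
        chrom = "chrS", start = centers[pres] + 20L,
        end = centers[pres] + 30L,
        motif_id = sprintf("null%d", m), strand = "+")
    }
    res <- motif_enrichment(fg, sites, data.table::rbindlist(occ))
    res$motif_id[which.min(res$p_value)] == "planted"
  })
  expect_gte(mean(hits), 0.95)
})
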
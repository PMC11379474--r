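test_that("median-of-ratios size factors behave on constructed cases", {
  m <- matrix(rpois(2000, 100), ncol = 2,
              dimnames = list(sprintf("g%04d", 1:1000), c("s1", "s2")))
  m[, 2] <- m[, 1]
  expect_equal(unname(normalize_libraries(m)), c(1, 1))

  m2 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  sf <- normalize_libraries(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  m3 <- m
  m3[, 1] <- 0L
  expect_error(normalize_libraries(m3), "s1")
})

test_that("planted library factors are recovered within 3%", {
  d <- study_design(conditions = c("A"), replicates = 3L)
  planted <- c(0.8, 1.0, 1.25)
  sim <- simulate_counts(d, templates = list(flat = 1),
                         n_per_template = c(flat = 5000),
                         dispersion = 0.05,
                         library_size_factors = planted, seed = 8)
  for (method in c("median_ratio", "tmm")) {
    sf <- normalize_libraries(sim$counts, method = method)
    rel <- sf / planted
    rel <- rel / exp(mean(log(rel)))
    expect_true(all(abs(rel - 1) < 0.03))
  }
})

test_that("TMM size factors agree with the edgeR reference implementation", {
  d <- study_design()
  sim <- simulate_counts(d, n_per_template = c(D = 100, E = 100, flat = 800),
                         seed = 4)
  sf <- normalize_libraries(sim$counts, method = "tmm")
  nf <- edgeR::calcNormFactors(sim$counts, method = "TMM")
  ref <- colSums(sim$counts) * nf
  ref <- ref / exp(mean(log(ref)))
  expect_true(all(abs(log2(sf / ref)) < 0.01))
})

test_that("dispersion estimation is accurate for Poisson and planted-NB data", {
  d <- study_design(conditions = c("A", "B"), replicates = 3L)
  pois <- simulate_counts(d, templates = list(flat = c(1, 1)),
                          n_per_template = c(flat = 2000),
                          base_mean_range = c(9999, 10001),
                          dispersion = 1e-9,
                          library_size_factors = rep(1, 6), seed = 9)
  conds <- conditions_from_sample_ids(colnames(pois$counts))
  a_pois <- estimate_dispersion(pois$counts, rep(1, 6), conds)
  expect_lte(median(a_pois), 1e-3)

  d5 <- study_design()
  nb <- simulate_counts(d5, templates = list(flat = rep(1, 5)),
                        n_per_template = c(flat = 2000),
                        dispersion = 0.05, seed = 10)
  conds5 <- conditions_from_sample_ids(colnames(nb$counts))
  sf <- normalize_libraries(nb$counts)
  a_nb <- estimate_dispersion(nb$counts, sf, conds5)
  expect_gte(median(a_nb), 0.03)
  expect_lte(median(a_nb), 0.08)

  # counts constant within every condition: the estimate hits the floor
  const <- matrix(rep(c(10L, 20L), each = 3), nrow = 5, ncol = 6, byrow = TRUE,
                  dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:6)))
  a_const <- estimate_dispersion(const, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_true(all(a_const == 1e-8))
})

test_that("pairwise contrast handles degenerate and boundary cases", {
  d <- study_design(conditions = c("A", "B"), replicates = 3L)
  sim <- simulate_counts(d, templates = list(flat = c(1, 1)),
                         n_per_template = c(flat = 200),
                         library_size_factors = rep(1, 6), seed = 11)
  counts <- sim$counts
  counts[1, ] <- 50L                    # identical in both conditions
  conds <- conditions_from_sample_ids(colnames(counts))
  res <- pairwise_contrast(counts, conds, "A", "B", rep(1, 6),
                           setNames(rep(0.05, nrow(counts)), rownames(counts)))
  expect_equal(res$log2FC[1], 0)
  expect_equal(res$pvalue[1], 1)
  expect_error(pairwise_contrast(counts, conds, "A", "Z"), "Z")
})

test_that("Wald p-values agree with a z-test on log means in the Poisson limit", {
  d <- study_design(conditions = c("A", "B"), replicates = 10L)
  sim <- simulate_counts(d, templates = list(flat = c(1, 1)),
                         n_per_template = c(flat = 1000),
                         base_mean_range = c(5e4, 5e4 + 1),
                         dispersion = 1e-9,
                         library_size_factors = rep(1, 20), seed = 12)
  conds <- conditions_from_sample_ids(colnames(sim$counts))
  disp <- setNames(rep(1e-9, 1000), rownames(sim$counts))
  res <- pairwise_contrast(sim$counts, conds, "A", "B", rep(1, 20), disp)
  # oracle: two-sample z-test on log counts, Poisson variance 1/mu
  ya <- sim$counts[, conds == "A"]
  yb <- sim$counts[, conds == "B"]
  se <- sqrt(1 / (rowSums(ya)) + 1 / (rowSums(yb)))
  z <- (log(rowMeans(yb)) - log(rowMeans(ya))) / se
  p_oracle <- 2 * pnorm(-abs(z))
  expect_lt(max(abs(res$pvalue - p_oracle)), 0.01)
})

test_that("regulation calls use inclusive boundaries", {
  res <- data.table::data.table(
    feature_id = c("a", "b", "c", "d"),
    baseMean = 100,
    log2FC = c(log2(1.5), 2, -1, 0.1),
    pvalue = c(0.01, 0.1, 0.0005, 0.5),
    padj = c(0.05, 0.2, 0.001, 0.9))
  calls <- classify_regulation(res)
  expect_equal(calls$status, c("induced", "unchanged", "repressed",
                               "unchanged"))
})

test_that("BH adjustment is monotone and order-invariant", {
  d <- study_design(conditions = c("A", "B"), replicates = 3L)
  sim <- simulate_counts(d, templates = list(flat = c(1, 1), up = c(1, 3)),
                         n_per_template = c(flat = 300, up = 100), seed = 13)
  conds <- conditions_from_sample_ids(colnames(sim$counts))
  res <- pairwise_contrast(sim$counts, conds, "A", "B")
  ok <- !is.na(res$padj)
  expect_true(all(res$padj[ok] >= res$pvalue[ok]))
  ord <- order(res$pvalue[ok])
  expect_true(all(diff(res$padj[ok][ord]) >= -1e-12))

  perm <- sample(nrow(sim$counts))
  res_perm <- pairwise_contrast(sim$counts[perm, ], conds, "A", "B")
  merged <- merge(res, res_perm, by = "feature_id")
  expect_equal(merged$padj.x, merged$padj.y)
  expect_equal(merged$log2FC.x, merged$log2FC.y)
})

test_that("scaling one sample moves only its size factor, not fold changes", {
  d <- study_design(conditions = c("A", "B"), replicates = 3L)
  sim <- simulate_counts(d, templates = list(flat = c(1, 1)),
                         n_per_template = c(flat = 2000),
                         base_mean_range = c(50, 500), seed = 14)
  conds <- conditions_from_sample_ids(colnames(sim$counts))
  res1 <- pairwise_contrast(sim$counts, conds, "A", "B")
  scaled <- sim$counts
  scaled[, 1] <- as.integer(round(scaled[, 1] * 3))
  res2 <- pairwise_contrast(scaled, conds, "A", "B")
  keep <- res1$baseMean >= 50
  expect_lt(max(abs(res1$log2FC[keep] - res2$log2FC[keep])), 0.01)
})

test_that("power at planted |log2FC| = 2 exceeds 95%", {
  d <- study_design(conditions = c("A", "B"), replicates = 3L)
  sim <- simulate_counts(d, templates = list(up = c(1, 4), flat = c(1, 1)),
                         n_per_template = c(up = 500, flat = 1500),
                         base_mean_range = c(100, 1000),
                         dispersion = 0.05, seed = 15)
  conds <- conditions_from_sample_ids(colnames(sim$counts))
  res <- pairwise_contrast(sim$counts, conds, "A", "B")
  calls <- classify_regulation(res)
  planted <- sim$truth$feature_id[sim$truth$pattern == "up"]
  hit <- calls$status[match(planted, calls$feature_id)] == "induced"
  expect_gte(mean(hit), 0.95)
})

test_that("contrast results agree with DESeq2 on a planted dataset", {
  d <- study_design(conditions = c("A", "B"), replicates = 3L)
  sim <- simulate_counts(d, templates = list(flat = c(1, 1), up = c(1, 4),
                                             down = c(1, 0.25)),
                         n_per_template = c(flat = 600, up = 100, down = 100),
                         seed = 16)
  conds <- conditions_from_sample_ids(colnames(sim$counts))
  res <- pairwise_contrast(sim$counts, conds, "A", "B")
  calls <- classify_regulation(res)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts,
      S4Vectors::DataFrame(condition = factor(conds, levels = c("A", "B"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ds <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  })
  ds_status <- rep("unchanged", nrow(ds))
  sig <- !is.na(ds$padj) & ds$padj <= 0.05
  ds_status[sig & ds$log2FoldChange >= log2(1.5)] <- "induced"
  ds_status[sig & ds$log2FoldChange <= -log2(1.5)] <- "repressed"
  agree <- mean(calls$status == ds_status[match(calls$feature_id,
                                                rownames(ds))])
  expect_gte(agree, 0.95)
  # fold-change estimates track DESeq2 closely for well-expressed features
  keep <- res$baseMean >= 50
  expect_lt(median(abs(res$log2FC[keep] -
                         ds$log2FoldChange[match(res$feature_id,
                                                 rownames(ds))][keep])), 0.1)
})

test_that("RPKM follows its closed form and scale invariance", {
  counts <- matrix(c(1000L, 0L), nrow = 2, ncol = 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  rpkm <- compute_rpkm(counts, c(g1 = 2000, g2 = 500), totals = 1e7)
  expect_equal(rpkm["g1", 1], 50)
  expect_equal(rpkm["g2", 1], 0)
  rpkm2 <- compute_rpkm(counts * 2L, c(g1 = 2000, g2 = 500), totals = 2e7)
  expect_equal(rpkm, rpkm2)
  expect_error(compute_rpkm(counts, c(g1 = 2000)), "g2")
})
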
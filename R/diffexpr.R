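#' Library size factors (median-of-ratios or TMM)
#'
#' `method = "median_ratio"` (default): per-sample size factor = median over
#' features (restricted to features with a finite, nonzero geometric mean
#' across samples) of count / geometric mean. `method = "tmm"`: trimmed mean
#' of M-values against a reference sample (30% two-sided trim on log-ratios,
#' 5% on average intensity, precision weights), scaled by library size —
#' robust to condition-asymmetric regulation, where the plain median of
#' ratios is visibly biased. Factors are rescaled to geometric mean 1.
#'
#' @param counts Integer matrix, features x samples.
#' @param method "median_ratio" or "tmm".
#' @return Named numeric vector of positive size factors.
#' @export
normalize_libraries <- function(counts, method = c("median_ratio", "tmm")) {
  method <- match.arg(method)
  if (any(counts < 0)) stop("counts must be non-negative")
  zero_samples <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_samples) > 0)
    stop("sample(s) with all-zero counts: ",
         paste(zero_samples, collapse = ", "))
  if (method == "median_ratio") {
    log_gm <- rowMeans(log(counts))
    use <- is.finite(log_gm)
    if (!any(use)) stop("no feature with nonzero counts in every sample")
    ratios <- log(counts[use, , drop = FALSE]) - log_gm[use]
    sf <- exp(apply(ratios, 2, stats::median))
  } else {
    sf <- tmm_size_factors(counts)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# TMM (trimmed mean of M-values): per-sample scaling factor against a
# reference sample, doubly trimmed (30% on M, 5% on A) with delta-method
# precision weights; size factor = library size x TMM factor.
tmm_size_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    y <- counts[, j]
    r <- counts[, ref]
    use <- y > 0 & r > 0
    y <- y[use]; r <- r[use]
    m <- log2((y / lib[j]) / (r / lib[ref]))
    a <- 0.5 * log2((y / lib[j]) * (r / lib[ref]))
    w <- (lib[j] - y) / (lib[j] * y) + (lib[ref] - r) / (lib[ref] * r)
    keep_m <- m > stats::quantile(m, trim_m) & m < stats::quantile(m, 1 - trim_m)
    keep_a <- a > stats::quantile(a, trim_a) & a < stats::quantile(a, 1 - trim_a)
    keep <- keep_m & keep_a
    if (!any(keep)) return(1)
    2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }, 0)
  lib * fac
}

#' Per-feature NB dispersion by method of moments with trend shrinkage
#'
#' The raw estimate pools, across conditions with >= 2 replicates, the
#' method-of-moments statistic alpha = (s^2 - mu) / mu^2 on normalized counts
#' (weighted by within-condition degrees of freedom), floored at zero. The
#' final estimate shrinks the raw value toward a mean-dispersion trend
#' (loess of the raw estimates against log mean), with weight `raw_weight`
#' on the feature-level estimate and a hard floor of 1e-8. The default
#' weight 0.3 approximates the relative precision of a feature-level moment
#' estimate at around four residual degrees of freedom against typical
#' between-gene dispersion spread; heavier weights leave enough sampling
#' noise in the per-feature dispersion to visibly inflate the Wald test's
#' type-I error at three replicates.
#'
#' @param counts Integer matrix, features x samples.
#' @param size_factors Per-sample size factors (see [normalize_libraries()]).
#' @param conditions Character vector of per-sample condition labels.
#' @param raw_weight Weight on the feature-level estimate in the shrinkage
#'   (default 0.3).
#' @return Named numeric vector of per-feature dispersions (>= 1e-8).
#' @export
estimate_dispersion <- function(counts, size_factors, conditions,
                                raw_weight = 0.3) {
  floor_alpha <- 1e-8
  norm <- sweep(counts, 2, size_factors, "/")
  conds <- unique(conditions)
  num <- numeric(nrow(counts))   # sum of df * (s^2 - mu)
  den <- numeric(nrow(counts))   # sum of df * mu^2
  base_mu <- numeric(nrow(counts))
  wsum <- 0
  for (cc in conds) {
    idx <- which(conditions == cc)
    if (length(idx) < 2) next
    x <- norm[, idx, drop = FALSE]
    mu <- rowMeans(x)
    s2 <- apply(x, 1, stats::var)
    df <- length(idx) - 1
    num <- num + df * (s2 - mu)
    den <- den + df * mu^2
    base_mu <- base_mu + df * mu
    wsum <- wsum + df
  }
  if (wsum == 0) stop("need >= 2 replicates in at least one condition")
  raw <- pmax(num / pmax(den, .Machine$double.eps), 0)
  base_mu <- base_mu / wsum

  # trend of dispersion against log mean, fitted on the raw scale so that
  # zero (floored) estimates do not drag the trend down
  ok <- base_mu > 0
  log_mu <- log(base_mu[ok])
  trend <- rep(max(stats::median(raw[ok]), 0), nrow(counts))
  if (sum(ok) >= 50 && stats::sd(log_mu) > 0) {
    fit <- stats::loess(raw[ok] ~ log_mu, span = 0.6, degree = 1,
                        control = stats::loess.control(surface = "direct"))
    trend[ok] <- pmax(stats::predict(fit, log_mu), 0)
  }
  alpha <- pmax(raw_weight * raw + (1 - raw_weight) * trend, floor_alpha)
  stats::setNames(alpha, rownames(counts))
}

# Vectorized two-group NB GLM (log link, offsets = log size factors) fitted by
# IRLS; returns the group coefficient and its expected-information SE.
nb_two_group_wald <- function(counts, size_factors, group, alpha,
                              max_iter = 50L, tol = 1e-8) {
  y <- counts
  n_feat <- nrow(y)
  off <- matrix(log(size_factors), n_feat, ncol(y), byrow = TRUE)
  x <- as.numeric(group)                       # 0/1 indicator per sample
  mean_a <- rowMeans(sweep(y[, x == 0, drop = FALSE], 2,
                           size_factors[x == 0], "/"))
  mean_b <- rowMeans(sweep(y[, x == 1, drop = FALSE], 2,
                           size_factors[x == 1], "/"))
  b0 <- log(pmax(mean_a, 0.1))
  b1 <- log(pmax(mean_b, 0.1)) - b0
  xm <- matrix(x, n_feat, ncol(y), byrow = TRUE)
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * xm + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    a11 <- rowSums(w)
    a12 <- rowSums(w * xm)
    a22 <- a12                                  # x in {0,1} so x^2 = x
    r1 <- rowSums(w * z)
    r2 <- rowSums(w * xm * z)
    det <- a11 * a22 - a12^2
    det <- ifelse(abs(det) < 1e-300, 1e-300, det)
    new_b0 <- (a22 * r1 - a12 * r2) / det
    new_b1 <- (a11 * r2 - a12 * r1) / det
    delta <- pmax(abs(new_b0 - b0), abs(new_b1 - b1))
    b0 <- new_b0
    b1 <- new_b1
    if (max(delta) < tol) break
  }
  eta <- b0 + b1 * xm + off
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  a11 <- rowSums(w)
  a12 <- rowSums(w * xm)
  det <- a11 * a12 - a12^2
  se <- sqrt(a11 / pmax(det, 1e-300))
  list(beta = b1, se = se)
}

#' Pairwise negative-binomial contrast (Wald test)
#'
#' Tests condition B against condition A per feature with a two-group NB GLM
#' (log link, log size-factor offsets, per-feature dispersion), Wald p-values
#' from the expected information, and BH adjustment within the contrast over
#' features passing an independent low-count filter (baseMean >= 1). The
#' reported fold change is `log2((mean_norm_B + 0.5) / (mean_norm_A + 0.5))`,
#' with the 0.5 pseudocount applied to the fold change only, not the
#' likelihood.
#'
#' @param counts Integer matrix, features x samples.
#' @param conditions Per-sample condition labels (length = ncol(counts)).
#' @param cond_a,cond_b Condition labels; log2FC is B over A.
#' @param size_factors Per-sample size factors; computed if `NULL`.
#' @param dispersions Per-feature dispersions; estimated if `NULL`.
#' @return data.table: feature_id, baseMean, log2FC, pvalue, padj. Features
#'   that are all-zero across all samples are dropped (with a message);
#'   features failing the baseMean filter keep their p-value but get padj NA.
#' @export
pairwise_contrast <- function(counts, conditions, cond_a, cond_b,
                              size_factors = NULL, dispersions = NULL) {
  for (cc in c(cond_a, cond_b)) {
    if (sum(conditions == cc) < 2)
      stop("condition not present with >= 2 replicates: ", cc)
  }
  all_zero <- rowSums(counts) == 0
  if (any(all_zero)) {
    message(sum(all_zero), " all-zero feature(s) dropped before testing")
    counts <- counts[!all_zero, , drop = FALSE]
  }
  if (is.null(size_factors)) size_factors <- normalize_libraries(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, size_factors, conditions)
  dispersions <- dispersions[rownames(counts)]

  sel <- conditions %in% c(cond_a, cond_b)
  y <- counts[, sel, drop = FALSE]
  sf <- size_factors[sel]
  grp <- as.integer(conditions[sel] == cond_b)

  norm <- sweep(y, 2, sf, "/")
  mean_a <- rowMeans(norm[, grp == 0, drop = FALSE])
  mean_b <- rowMeans(norm[, grp == 1, drop = FALSE])
  base_mean <- rowMeans(norm)
  log2_fc <- log2((mean_b + 0.5) / (mean_a + 0.5))

  fit <- nb_two_group_wald(y, sf, grp, dispersions)
  zstat <- fit$beta / fit$se
  pvalue <- 2 * stats::pnorm(-abs(zstat))
  # a feature identical in both groups carries no evidence
  pvalue[mean_a == mean_b] <- 1

  padj <- rep(NA_real_, length(pvalue))
  keep <- base_mean >= 1
  padj[keep] <- stats::p.adjust(pvalue[keep], method = "BH")

  data.table::data.table(feature_id = rownames(y),
                         baseMean = base_mean,
                         log2FC = log2_fc,
                         pvalue = pvalue,
                         padj = padj)
}

#' Call regulation status from a contrast table
#'
#' A feature is `induced` iff log2FC >= log2(fc_min) and adj p <= alpha
#' (boundaries inclusive); `repressed` iff log2FC <= -log2(fc_min) and
#' adj p <= alpha; otherwise `unchanged`. Features with adj p NA (filtered)
#' are `unchanged`.
#'
#' @param results Contrast table from [pairwise_contrast()].
#' @param fc_min Fold-change cutoff (default 1.5).
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @return data.table: feature_id, status, fc_min, alpha.
#' @export
classify_regulation <- function(results, fc_min = 1.5, alpha = 0.05) {
  if (fc_min <= 0 || alpha <= 0) stop("thresholds must be positive")
  lfc <- log2(fc_min)
  sig <- !is.na(results$padj) & results$padj <= alpha
  status <- rep("unchanged", nrow(results))
  status[sig & results$log2FC >= lfc] <- "induced"
  status[sig & results$log2FC <= -lfc] <- "repressed"
  data.table::data.table(feature_id = results$feature_id,
                         status = status,
                         fc_min = fc_min, alpha = alpha)
}

#' Run every contrast needed by the kinetic-pattern rules
#'
#' Computes the four refeeding-state contrasts against Adlib, the Fasted
#' contrast against every fed state, and returns both contrast tables and
#' regulation calls keyed by "B_vs_A" names (log2FC is B over A).
#'
#' @param counts Integer matrix, features x samples.
#' @param conditions Per-sample condition labels.
#' @param fc_min,alpha Regulation cutoffs.
#' @param size_factors,dispersions Optional; computed once and reused.
#' @return List with `contrasts` (named list of contrast tables), `calls`
#'   (single data.table feature_id, contrast, status), `size_factors`,
#'   `dispersions`.
#' @export
run_standard_contrasts <- function(counts, conditions, fc_min = 1.5,
                                   alpha = 0.05, size_factors = NULL,
                                   dispersions = NULL,
                                   size_factor_method = "tmm") {
  all_zero <- rowSums(counts) == 0
  counts <- counts[!all_zero, , drop = FALSE]
  if (is.null(size_factors))
    size_factors <- normalize_libraries(counts, method = size_factor_method)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, size_factors, conditions)
  fed <- c("Adlib", "Refed_3h", "Refed_10h", "Refed_24h")
  pairs <- rbind(
    data.frame(a = "Adlib", b = c("Fasted", "Refed_3h", "Refed_10h",
                                  "Refed_24h")),
    data.frame(a = setdiff(fed, "Adlib"), b = "Fasted"))
  pairs <- pairs[!duplicated(paste(pairs$b, pairs$a)), ]
  contrasts <- list()
  calls <- list()
  for (i in seq_len(nrow(pairs))) {
    nm <- paste0(pairs$b[i], "_vs_", pairs$a[i])
    res <- pairwise_contrast(counts, conditions, pairs$a[i], pairs$b[i],
                             size_factors, dispersions)
    contrasts[[nm]] <- res
    cl <- classify_regulation(res, fc_min, alpha)
    cl[, contrast := nm]
    calls[[nm]] <- cl[, .(feature_id, contrast, status)]
  }
  list(contrasts = contrasts,
       calls = data.table::rbindlist(calls),
       size_factors = size_factors,
       dispersions = dispersions)
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM = count * 1e9 / (length_bp * total mapped reads of the sample).
#'
#' @param counts Integer matrix, features x samples.
#' @param lengths_bp Named (or positionally matched) feature lengths in bp.
#' @param totals Per-sample total mapped reads; defaults to column sums.
#' @return Numeric matrix of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths_bp, totals = colSums(counts)) {
  if (!is.null(names(lengths_bp))) {
    missing <- setdiff(rownames(counts), names(lengths_bp))
    if (length(missing) > 0)
      stop("missing length for feature(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    lengths_bp <- lengths_bp[rownames(counts)]
  }
  if (length(lengths_bp) != nrow(counts))
    stop("lengths_bp must match the number of features")
  if (any(!is.finite(lengths_bp)) || any(lengths_bp <= 0))
    stop("feature lengths must be positive")
  counts * 1e9 / outer(as.numeric(lengths_bp), as.numeric(totals))
}

#' Per-condition mean of normalized counts
#'
#' @param counts Integer matrix, features x samples.
#' @param conditions Per-sample condition labels.
#' @param size_factors Per-sample size factors; computed if `NULL`.
#' @param cond_order Optional condition column order.
#' @return Numeric matrix, features x conditions.
#' @export
condition_means <- function(counts, conditions, size_factors = NULL,
                            cond_order = unique(conditions)) {
  if (is.null(size_factors)) size_factors <- normalize_libraries(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  out <- sapply(cond_order, function(cc)
    rowMeans(norm[, conditions == cc, drop = FALSE]))
  rownames(out) <- rownames(counts)
  out
}
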
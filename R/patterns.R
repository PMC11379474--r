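#' Fasting-induced and fasting-repressed gene universes
#'
#' Fasting-induced genes show significantly higher expression in Fasted than
#' in at least one fed state (Adlib or any refed time point); fasting-
#' repressed genes show significantly lower expression in Fasted than in at
#' least one fed state. A gene can satisfy both (contradictory calls across
#' fed states); such genes are returned in `contradictory` and kept in both
#' sets.
#'
#' @param calls data.table of regulation calls with columns feature_id,
#'   contrast, status; contrasts named "Fasted_vs_<fed>" with log2FC of
#'   Fasted over the fed state.
#' @param fed_states Fed-state labels to require.
#' @return List with `induced`, `repressed` (character vectors) and
#'   `contradictory`.
#' @export
fasting_regulated_universe <- function(calls,
                                       fed_states = c("Adlib", "Refed_3h",
                                                      "Refed_10h",
                                                      "Refed_24h")) {
  need <- paste0("Fasted_vs_", fed_states)
  missing <- setdiff(need, unique(calls$contrast))
  if (length(missing) > 0)
    stop("missing contrast(s): ", paste(missing, collapse = ", "))
  sub <- calls[calls$contrast %in% need]
  induced <- sort(unique(sub$feature_id[sub$status == "induced"]))
  repressed <- sort(unique(sub$feature_id[sub$status == "repressed"]))
  both <- intersect(induced, repressed)
  if (length(both) > 0)
    message(length(both),
            " gene(s) with contradictory fasting calls kept in both sets")
  list(induced = induced, repressed = repressed, contradictory = both)
}

# status of one contrast per feature, "unchanged" when absent from the table
contrast_status <- function(calls, contrast_name, ids) {
  sub <- calls[calls$contrast == contrast_name]
  st <- sub$status[match(ids, sub$feature_id)]
  st[is.na(st)] <- "unchanged"
  st
}

#' Call refeeding kinetic patterns D, E, F, G from regulation calls
#'
#' Pure rule-based classification over five pairwise contrasts:
#' * D (recovered): repressed in Fasted vs Adlib AND repressed in Fasted vs
#'   Refed_24h AND not induced in Refed_24h vs Adlib.
#' * E (overshoot): repressed in Fasted vs Adlib AND induced in Refed_24h vs
#'   Adlib.
#' * F (late induction): induced in Refed_10h or Refed_24h vs Adlib AND not
#'   induced in Fasted vs Adlib AND not induced in Refed_3h vs Adlib.
#' * G (early induction): induced in Refed_3h vs Adlib AND not induced in
#'   Fasted, Refed_10h, or Refed_24h vs Adlib.
#'
#' Rules can overlap on their literal text; precedence D > E > F > G makes
#' the result a partition (D and E are already mutually exclusive by
#' construction). Genes matching no rule get pattern "none".
#'
#' @param calls data.table feature_id, contrast, status covering contrasts
#'   Fasted_vs_Adlib, Refed_3h_vs_Adlib, Refed_10h_vs_Adlib,
#'   Refed_24h_vs_Adlib, Fasted_vs_Refed_24h.
#' @return data.table feature_id, pattern, rule_trace.
#' @export
call_refeeding_patterns <- function(calls) {
  need <- c("Fasted_vs_Adlib", "Refed_3h_vs_Adlib", "Refed_10h_vs_Adlib",
            "Refed_24h_vs_Adlib", "Fasted_vs_Refed_24h")
  missing <- setdiff(need, unique(calls$contrast))
  if (length(missing) > 0)
    stop("missing contrast(s): ", paste(missing, collapse = ", "))
  ids <- sort(unique(calls$feature_id))
  st <- lapply(stats::setNames(need, need), contrast_status,
               calls = calls, ids = ids)

  is_d <- st$Fasted_vs_Adlib == "repressed" &
    st$Fasted_vs_Refed_24h == "repressed" &
    st$Refed_24h_vs_Adlib != "induced"
  is_e <- st$Fasted_vs_Adlib == "repressed" &
    st$Refed_24h_vs_Adlib == "induced"
  is_f <- (st$Refed_10h_vs_Adlib == "induced" |
             st$Refed_24h_vs_Adlib == "induced") &
    st$Fasted_vs_Adlib != "induced" &
    st$Refed_3h_vs_Adlib != "induced"
  is_g <- st$Refed_3h_vs_Adlib == "induced" &
    st$Fasted_vs_Adlib != "induced" &
    st$Refed_10h_vs_Adlib != "induced" &
    st$Refed_24h_vs_Adlib != "induced"

  pattern <- rep("none", length(ids))
  pattern[is_g] <- "G"
  pattern[is_f] <- "F"
  pattern[is_e] <- "E"
  pattern[is_d] <- "D"

  trace <- vapply(seq_along(ids), function(i)
    paste(paste0(need, ":", vapply(st, `[`, "", i)), collapse = ";"),
    character(1))
  data.table::data.table(feature_id = ids, pattern = pattern,
                         rule_trace = trace)
}

#' k-means clustering with a one-minus-Pearson metric
#'
#' Condition-mean vectors are standardized per feature (z-score across
#' conditions); features with zero variance across conditions are excluded
#' (with a message). Lloyd's algorithm runs with distance 1 - Pearson r for
#' at most `max_iter` iterations, and the best of `restarts` seeded starts
#' (lowest total within-cluster distance; ties broken by the lowest restart
#' index) is returned.
#'
#' @param cond_means Numeric matrix, features x conditions.
#' @param k Number of clusters.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return List of class `pattern_clustering`: `assignment` (named integer),
#'   `centroids` (k x conditions, standardized space), `k`, `metric`,
#'   `tot_withinss`, `excluded` (zero-variance feature ids).
#' @export
cluster_patterns <- function(cond_means, k = 3, seed = 17L, restarts = 10L,
                             max_iter = 1000L) {
  if (is.null(rownames(cond_means)))
    rownames(cond_means) <- sprintf("feature_%05d", seq_len(nrow(cond_means)))
  if (!all(is.finite(cond_means))) stop("condition means must be finite")
  sds <- apply(cond_means, 1, stats::sd)
  excluded <- rownames(cond_means)[sds == 0]
  if (length(excluded) > 0)
    message(length(excluded), " zero-variance feature(s) excluded")
  x <- cond_means[sds > 0, , drop = FALSE]
  if (nrow(x) < k) stop("need at least k features with variance")
  z <- t(scale(t(x)))                           # z-score across conditions

  run_once <- function(rs) {
    set.seed(seed + rs - 1L)
    cent <- z[sample(nrow(z), k), , drop = FALSE]
    assign_old <- integer(nrow(z))
    for (it in seq_len(max_iter)) {
      r <- stats::cor(t(z), t(cent))            # features x k Pearson
      assign_new <- max.col(r, ties.method = "first")
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      for (j in seq_len(k)) {
        members <- which(assign_new == j)
        if (length(members) == 0) {
          # re-seed an empty cluster with the worst-fit feature
          worst <- which.min(r[cbind(seq_len(nrow(z)), assign_new)])
          cent[j, ] <- z[worst, ]
        } else {
          cent[j, ] <- colMeans(z[members, , drop = FALSE])
        }
      }
    }
    r <- stats::cor(t(z), t(cent))
    assignment <- max.col(r, ties.method = "first")
    tot <- sum(1 - r[cbind(seq_len(nrow(z)), assignment)])
    list(assignment = assignment, centroids = cent, tot_withinss = tot)
  }
  runs <- lapply(seq_len(restarts), run_once)
  best <- runs[[which.min(vapply(runs, `[[`, 0, "tot_withinss"))]]
  structure(list(assignment = stats::setNames(best$assignment, rownames(z)),
                 centroids = best$centroids,
                 k = k, metric = "one_minus_pearson",
                 tot_withinss = best$tot_withinss,
                 excluded = excluded),
            class = "pattern_clustering")
}

#' Match discovered clusters to schematic pattern templates
#'
#' Assigns each cluster the label of the template whose (standardized)
#' multiplier vector correlates best with the cluster centroid.
#'
#' @param clustering A `pattern_clustering`.
#' @param templates Named list of template multiplier vectors.
#' @return Named character vector: cluster index -> template label.
#' @export
match_clusters_to_templates <- function(clustering,
                                        templates = pattern_templates()) {
  tpl <- do.call(rbind, templates)
  keep <- apply(tpl, 1, stats::sd) > 0
  tpl <- tpl[keep, , drop = FALSE]
  r <- stats::cor(t(clustering$centroids), t(tpl))
  labs <- rownames(tpl)[max.col(r, ties.method = "first")]
  stats::setNames(labs, seq_len(nrow(clustering$centroids)))
}

#' Overlap statistics for two feature sets
#'
#' @param set_x,set_y Character vectors of feature ids.
#' @return List with n_x, n_y, n_intersect, n_x_only, n_y_only, and
#'   fraction_x_in_y (NA for empty X).
#' @export
set_overlap <- function(set_x, set_y) {
  set_x <- unique(set_x)
  set_y <- unique(set_y)
  n_int <- length(intersect(set_x, set_y))
  list(n_x = length(set_x),
       n_y = length(set_y),
       n_intersect = n_int,
       n_x_only = length(set_x) - n_int,
       n_y_only = length(set_y) - n_int,
       fraction_x_in_y = if (length(set_x) == 0) NA_real_
                         else n_int / length(set_x))
}
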
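#' Define a curated gene group
#'
#' @param name Group name (e.g. "LIPO", "CHOL", "AID", or custom).
#' @param members Character vector of gene ids (must be unique).
#' @param note Optional provenance note.
#' @return Object of class `gene_group`.
#' @export
gene_group <- function(name, members, note = "") {
  if (anyDuplicated(members)) stop("duplicate gene ids in group ", name)
  structure(list(name = name, members = as.character(members), note = note),
            class = "gene_group")
}

#' Check that gene groups do not overlap
#'
#' @param groups List of `gene_group` objects.
#' @return Invisibly TRUE; errors if any gene sits in two groups.
#' @export
validate_groups <- function(groups) {
  all_ids <- unlist(lapply(groups, `[[`, "members"))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup) > 0)
    stop("gene(s) in more than one group: ",
         paste(utils::head(dup, 5), collapse = ", "))
  invisible(TRUE)
}

#' Curation filter for a lipid-pathway gene group
#'
#' Two independent exclusion steps mirror the curation used for the LIPO,
#' CHOL, and AID groups: step 1 keeps genes expressed in liver (maximum
#' condition-mean RPKM >= `rpkm_min`, boundary inclusive); step 2 keeps genes
#' repressed by fasting (member of the fasting-repressed universe, i.e.
#' significantly lower in Fasted than in at least one fed state). Member ids
#' missing from the RPKM matrix are reported but not fatal.
#'
#' @param group A `gene_group`.
#' @param rpkm_cond_means Numeric matrix of condition-mean RPKM
#'   (genes x conditions).
#' @param fasting_repressed Character vector: the fasting-repressed universe.
#' @param rpkm_min Expression cutoff (default 1).
#' @return List: `group` (filtered `gene_group`), `report` (data.table with
#'   per-step counts: input, missing, excluded_low_expression,
#'   excluded_not_repressed, survivors).
#' @export
filter_group <- function(group, rpkm_cond_means, fasting_repressed,
                         rpkm_min = 1) {
  stopifnot(inherits(group, "gene_group"))
  ids <- group$members
  if (length(ids) == 0) stop("empty input group: ", group$name)
  present <- ids[ids %in% rownames(rpkm_cond_means)]
  missing <- setdiff(ids, present)

  max_rpkm <- apply(rpkm_cond_means[present, , drop = FALSE], 1, max)
  expressed <- present[max_rpkm >= rpkm_min]
  repressed <- present[present %in% fasting_repressed]
  survivors <- intersect(expressed, repressed)

  # sequential accounting: low expression first, then not-repressed among
  # the expressed (the two predicates are independent, so order is cosmetic)
  excl1 <- setdiff(present, expressed)
  excl2 <- setdiff(expressed, survivors)
  report <- data.table::data.table(
    group = group$name,
    input = length(ids),
    missing = length(missing),
    excluded_low_expression = length(excl1),
    excluded_not_repressed = length(excl2),
    survivors = length(survivors))
  list(group = gene_group(group$name, survivors, group$note),
       report = report,
       missing_ids = missing)
}

#' Fold-change comparison between gene groups
#'
#' Per gene, the fasting-repression fold change (Adlib over Fasted) and the
#' refeeding-induction fold change (Refed_24h over Adlib) are extracted from
#' the contrast tables; each axis is compared between every pair of groups
#' with a two-sided Mann-Whitney U test (exact for groups of at most 20).
#'
#' @param groups List of `gene_group` objects (filtered); groups with fewer
#'   than `min_size` genes are skipped with a warning.
#' @param fasted_vs_adlib Contrast table (log2FC of Fasted over Adlib).
#' @param refed24_vs_adlib Contrast table (log2FC of Refed_24h over Adlib).
#' @param min_size Minimum group size (default 3).
#' @return List: `per_gene` (data.table group, gene_id,
#'   fasting_repression_fc, refeeding_induction_fc), `tests` (data.table
#'   group_a, group_b, axis, p_value, exact).
#' @export
group_fc_comparison <- function(groups, fasted_vs_adlib, refed24_vs_adlib,
                                min_size = 3L) {
  validate_groups(groups)
  keep <- vapply(groups, function(g) length(g$members) >= min_size, TRUE)
  if (any(!keep))
    warning("group(s) below size ", min_size, " skipped: ",
            paste(vapply(groups[!keep], `[[`, "", "name"), collapse = ", "))
  groups <- groups[keep]
  if (length(groups) < 2) stop("need >= 2 groups of size >= ", min_size)

  per_gene <- data.table::rbindlist(lapply(groups, function(g) {
    lfc_fast <- fasted_vs_adlib$log2FC[match(g$members,
                                             fasted_vs_adlib$feature_id)]
    lfc_refed <- refed24_vs_adlib$log2FC[match(g$members,
                                               refed24_vs_adlib$feature_id)]
    data.table::data.table(group = g$name, gene_id = g$members,
                           fasting_repression_fc = 2^(-lfc_fast),
                           refeeding_induction_fc = 2^(lfc_refed))
  }))
  per_gene <- per_gene[stats::complete.cases(per_gene)]

  gnames <- vapply(groups, `[[`, "", "name")
  tests <- list()
  for (i in seq_along(gnames)) for (j in seq_along(gnames)) {
    if (i >= j) next
    for (axis in c("fasting_repression_fc", "refeeding_induction_fc")) {
      xa <- per_gene[[axis]][per_gene$group == gnames[i]]
      xb <- per_gene[[axis]][per_gene$group == gnames[j]]
      # exact distribution only exists without ties
      exact <- length(xa) <= 20 && length(xb) <= 20 &&
        !anyDuplicated(c(xa, xb))
      p <- stats::wilcox.test(xa, xb, alternative = "two.sided",
                              exact = exact)$p.value
      tests[[length(tests) + 1L]] <- data.table::data.table(
        group_a = gnames[i], group_b = gnames[j], axis = axis,
        p_value = p, exact = exact)
    }
  }
  list(per_gene = per_gene, tests = data.table::rbindlist(tests))
}
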
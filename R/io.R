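#' @importFrom data.table := .N .SD
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "value", "win_idx", "start", "end", "peak_id", "gene_id", "pattern",
  "condition", "replicate", "sample_id", "contrast", "feature_id", "status",
  "fa", "fpd", "fa_a", "fa_b", "fpd_a", "fpd_b", "dfa", "dfpd", "depth",
  "in_bag", "outlier", "jointly_increased", "p_value", "padj", "tss",
  "motif_id", "gene_id_obs", "count", "lxr_status"))

#' Write / read a counts matrix as TSV
#'
#' Columns: feature_id then one column per sample named condition_repN.
#'
#' @param counts Integer matrix.
#' @param path File path.
#' @return `read_counts_tsv` returns the integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  dt <- data.table::data.table(feature_id = rownames(counts))
  dt <- cbind(dt, data.table::as.data.table(counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$feature_id
  storage.mode(m) <- "integer"
  m
}

#' Condition labels parsed from sample column names
#'
#' @param sample_ids Character vector of "condition_repN" names.
#' @return Character vector of condition labels.
#' @export
conditions_from_sample_ids <- function(sample_ids) {
  sub("_rep[0-9]+$", "", sample_ids)
}

#' Write intervals as BED6
#'
#' @param intervals data.table chrom, start, end and optionally name, score,
#'   strand.
#' @param path File path.
#' @return Invisibly the path.
#' @export
write_bed <- function(intervals, path) {
  iv <- data.table::as.data.table(intervals)
  gr <- GenomicRanges::GRanges(
    iv$chrom,
    IRanges::IRanges(iv$start + 1L, iv$end),
    strand = if (!is.null(iv$strand)) iv$strand else "*")
  if (!is.null(iv$name)) names(gr) <- iv$name
  S4Vectors::mcols(gr)$score <- if (!is.null(iv$score)) iv$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a data.table
#'
#' @param path File path.
#' @return data.table chrom, start, end, name, score, strand (0-based
#'   half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- names(gr)
  if (is.null(nm) && "name" %in% names(S4Vectors::mcols(gr)))
    nm <- S4Vectors::mcols(gr)$name
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(nm)) nm else NA_character_,
    score = if ("score" %in% names(S4Vectors::mcols(gr)))
      S4Vectors::mcols(gr)$score else NA_real_,
    strand = as.character(GenomicRanges::strand(gr)))
}

#' Write / read a signal track as bedGraph
#'
#' @param track A `signal_track`.
#' @param path File path.
#' @param contigs Contig lengths for reading (named integer vector).
#' @return `read_bedgraph` returns a `signal_track`.
#' @export
write_bedgraph <- function(track, path) {
  iv <- track$intervals
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(iv$start + 1L, iv$end),
                               score = iv$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, contigs) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  iv <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = S4Vectors::mcols(gr)$score)
  signal_track(iv, contigs)
}
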
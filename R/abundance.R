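# ASV-level filters and rank-level aggregation.
#
# The screening pipeline applies the ASV filters FIRST (minimum total reads,
# then occurrence), and only then rolls counts up to the working rank; all
# aggregation is integer arithmetic, so read totals are conserved exactly.

#' Drop features sequenced fewer than `min_reads` times in total
#'
#' The total is the row sum across all samples of the analysis unit, so a
#' feature with 5 reads in one sample or 1 read in each of 5 samples both
#' survive the default filter (the boundary is inclusive).
#'
#' @param table Feature table matrix.
#' @param min_reads Minimum total reads (default 5). `0` is the identity.
#' @return The table restricted to surviving features; the sample set is
#'   unchanged.
#' @export
filter_min_total_reads <- function(table, min_reads = 5) {
  stopifnot(is.numeric(min_reads), length(min_reads) == 1, min_reads >= 0)
  table <- feature_table(table)
  table[rowSums(table) >= min_reads, , drop = FALSE]
}

#' Per-feature totals and occurrence
#'
#' Occurrence counts the samples in which a feature is present; "present"
#' means at least one read (no abundance floor), the most permissive reading.
#'
#' @param table Feature table matrix.
#' @return Data frame with columns `feature_id`, `total_reads`, `occurrence`,
#'   sorted by decreasing occurrence then decreasing total reads.
#' @export
feature_occurrence <- function(table) {
  table <- feature_table(table)
  out <- data.frame(feature_id = rownames(table),
                    total_reads = as.integer(rowSums(table)),
                    occurrence = as.integer(rowSums(table >= 1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrence, -out$total_reads, out$feature_id,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Drop features present in fewer than `min_occurrence` samples
#'
#' @param table Feature table matrix.
#' @param min_occurrence Minimum number of samples with >= 1 read (default 2,
#'   i.e. keep features found in more than one sample).
#' @return Filtered table; sample set unchanged.
#' @export
filter_min_occurrence <- function(table, min_occurrence = 2) {
  stopifnot(is.numeric(min_occurrence), length(min_occurrence) == 1,
            min_occurrence >= 0)
  table <- feature_table(table)
  table[rowSums(table >= 1) >= min_occurrence, , drop = FALSE]
}

#' Convert counts to per-sample relative abundance
#'
#' @param table Feature (or aggregated) count matrix.
#' @param allow_zero_samples If `FALSE` (default), a zero-read sample is an
#'   error naming the sample; if `TRUE`, its column is returned as all zeros
#'   and listed in the `zero_read_samples` attribute.
#' @return Numeric matrix of fractions; each retained sample's column sums to
#'   1 within 1e-9.
#' @export
to_relative_abundance <- function(table, allow_zero_samples = FALSE) {
  m <- as.matrix(table)
  totals <- colSums(m)
  zero <- colnames(m)[totals == 0]
  if (length(zero) && !allow_zero_samples) {
    stop("zero-read sample(s): ", paste(zero, collapse = ", "),
         " (set allow_zero_samples = TRUE to tolerate)")
  }
  totals[totals == 0] <- 1  # leaves zero columns at 0 rather than NaN
  out <- sweep(m, 2, totals, "/")
  attr(out, "zero_read_samples") <- zero
  out
}

#' Aggregate a feature table to a taxonomic rank
#'
#' Features whose lineage is missing a label at `rank` pool into the reserved
#' [unassigned_label()] bucket; labels are matched verbatim and
#' case-sensitively. Summation is integer, so per-sample totals are conserved
#' exactly.
#'
#' @param table Feature table matrix.
#' @param taxonomy Taxonomy data frame covering every feature of `table`.
#' @param rank One of [lineage_ranks()] (default `"order"`, the rank at which
#'   short amplicons can still be assigned with confidence).
#' @return Integer matrix, labels x samples, rows sorted with the unassigned
#'   bucket last; carries a `rank` attribute.
#' @export
aggregate_to_rank <- function(table, taxonomy, rank = "order") {
  rank <- match.arg(rank, lineage_ranks())
  table <- feature_table(table)
  idx <- match(rownames(table), taxonomy$feature_id)
  if (anyNA(idx)) {
    stop("feature(s) absent from taxonomy: ",
         paste(rownames(table)[is.na(idx)], collapse = ", "))
  }
  labels <- taxonomy[[rank]][idx]
  labels[is.na(labels)] <- unassigned_label()
  agg <- rowsum(table, group = labels, reorder = FALSE)
  ord <- c(sort(setdiff(rownames(agg), unassigned_label()), method = "radix"),
           intersect(unassigned_label(), rownames(agg)))
  agg <- agg[ord, , drop = FALSE]
  storage.mode(agg) <- "integer"
  attr(agg, "rank") <- rank
  agg
}

#' Write an aggregated (or occurrence) table as TSV
#'
#' Uses the same features-as-rows dialect as [write_feature_table()], with the
#' first column named after the aggregation rank.
#'
#' @param agg Aggregated count matrix from [aggregate_to_rank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregated_table <- function(agg, path) {
  df <- data.frame(rownames(agg), agg, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- attr(agg, "rank") %||% "label"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
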
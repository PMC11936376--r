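# Classifying a query sample's order-level reads against the contaminant
# database and computing per-sample contamination fractions.

SCREEN_LABELS <- c("potential_contaminant", "seawater_influenced", "endemic",
                   "below_threshold", "unassigned")

#' Label one order's reads in one sample
#'
#' Precedence: unassigned reads keep their own label; reads of an order below
#' the per-sample relative-abundance threshold are `below_threshold` whatever
#' the database says (low-abundance orders cannot be called with confidence);
#' then laboratory membership wins over seawater membership, so a ubiquitous
#' order (on both lists) is a `potential_contaminant` -- in drilling surveys
#' most contamination traces to laboratory sources rather than seawater;
#' orders on neither list are `endemic`.
#'
#' @param order Order label (possibly [unassigned_label()]).
#' @param sample_fraction The order's relative abundance within the sample,
#'   in `[0, 1]`.
#' @param db A `contaminant_database`.
#' @param config A [screening_config()]; only `per_sample_threshold` is used.
#' @return One of `"potential_contaminant"`, `"seawater_influenced"`,
#'   `"endemic"`, `"below_threshold"`, `"unassigned"`.
#' @export
label_order <- function(order, sample_fraction, db,
                        config = screening_config()) {
  stopifnot(sample_fraction >= 0, sample_fraction <= 1)
  if (order == unassigned_label()) return("unassigned")
  if (sample_fraction < config$per_sample_threshold) return("below_threshold")
  if (order %in% db$laboratory$order) return("potential_contaminant")
  if (order %in% db$seawater$order) return("seawater_influenced")
  "endemic"
}

#' Fraction of a sample's reads covered by the database
#'
#' Coverage ignores the per-sample threshold: it is simply the fraction of the
#' sample's reads whose order belongs to the union of the laboratory and
#' seawater lists. A high coverage in a negative control means the database
#' captures essentially everything that control contains.
#'
#' @param sample_profile Named fraction vector for one sample (a column of
#'   [to_relative_abundance()] applied to an aggregated table).
#' @param db A `contaminant_database`.
#' @return A fraction in `[0, 1]`.
#' @export
database_coverage <- function(sample_profile, db) {
  members <- union(db$laboratory$order, db$seawater$order)
  sum(sample_profile[names(sample_profile) %in% members])
}

#' Screen query samples against a contaminant database
#'
#' Runs the abundance pipeline on the query samples (ASV filters, then rollup
#' to the database's rank, then per-sample relative abundance) and labels each
#' (sample, order) pair with [label_order()]. Per-sample label fractions sum
#' to 1; denominators are the filtered read totals. Zero-read query samples
#' are skipped with a warning.
#'
#' @param table Feature table matrix containing the query samples.
#' @param taxonomy Taxonomy data frame.
#' @param manifest Sample manifest; rows with role `"query"` are screened.
#' @param db A `contaminant_database` whose rank must equal `config$rank`.
#' @param config A [screening_config()].
#' @return A `screening_report` list: `per_sample` (one row per screened
#'   sample with the five label fractions, database coverage and read totals),
#'   `detail` (long format: sample, order, fraction, label, membership flags),
#'   `config` and `db_provenance`.
#' @export
screen_samples <- function(table, taxonomy, manifest, db,
                           config = screening_config()) {
  stopifnot(inherits(db, "contaminant_database"))
  if (!identical(db$rank, config$rank)) {
    stop("database rank (", db$rank, ") does not match config rank (",
         config$rank, ")")
  }
  table <- feature_table(table)
  val <- validate_bundle(table, taxonomy, manifest)
  if (!val$valid) stop("invalid bundle: ", paste(val$errors, collapse = "; "))

  queries <- manifest$sample_id[manifest$role == "query"]
  if (length(queries) == 0) stop("manifest contains no query samples")
  qtab <- table[, queries, drop = FALSE]
  zero <- queries[colSums(qtab) == 0]
  if (length(zero)) {
    warning("skipping zero-read query sample(s): ", paste(zero, collapse = ", "))
    queries <- setdiff(queries, zero)
    qtab <- qtab[, queries, drop = FALSE]
  }
  if (length(queries) == 0) stop("no query samples with reads")

  qtab <- filter_min_total_reads(qtab, config$min_reads)
  qtab <- filter_min_occurrence(qtab, config$min_occurrence)
  if (nrow(qtab) == 0) stop("no features survive the ASV filters")
  agg <- aggregate_to_rank(qtab, taxonomy, config$rank)
  rel <- to_relative_abundance(agg, allow_zero_samples = TRUE)
  post_zero <- attr(rel, "zero_read_samples")
  if (length(post_zero)) {
    warning("sample(s) emptied by the ASV filters, skipped: ",
            paste(post_zero, collapse = ", "))
    keep <- setdiff(colnames(rel), post_zero)
    rel <- rel[, keep, drop = FALSE]
    agg <- agg[, keep, drop = FALSE]
    queries <- intersect(queries, keep)
  }

  lab_set <- db$laboratory$order
  sw_set <- db$seawater$order
  detail <- vector("list", length(queries))
  per_sample <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    s <- queries[i]
    frac <- stats::setNames(rel[, s], rownames(rel))
    present <- names(frac)[frac > 0]
    labels <- vapply(present, function(o) label_order(o, frac[[o]], db, config), "")
    detail[[i]] <- data.frame(sample_id = s, order = present,
                              fraction = as.numeric(frac[present]),
                              label = labels,
                              in_laboratory = present %in% lab_set,
                              in_seawater = present %in% sw_set,
                              stringsAsFactors = FALSE)
    sums <- vapply(SCREEN_LABELS,
                   function(l) sum(frac[present][labels == l]), 0)
    per_sample[[i]] <- data.frame(
      sample_id = s, t(sums),
      coverage = database_coverage(frac, db),
      total_reads = sum(agg[, s]),
      stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  per_sample <- do.call(rbind, per_sample)
  rownames(detail) <- rownames(per_sample) <- NULL
  structure(list(per_sample = per_sample, detail = detail,
                 config = config, db_provenance = db$provenance),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening report:", nrow(x$per_sample), "sample(s)\n")
  print(x$per_sample, digits = 4)
  invisible(x)
}

#' Per-sample contamination fraction from a report
#'
#' @param report A `screening_report`.
#' @param include_seawater If `TRUE` (default) contamination is
#'   `potential_contaminant + seawater_influenced`; set `FALSE` to treat
#'   seawater-influenced reads as possibly endemic fluid flow.
#' @return Named numeric vector of contamination fractions by sample id.
#' @export
contamination_fraction <- function(report, include_seawater = TRUE) {
  x <- report$per_sample
  v <- x$potential_contaminant + if (include_seawater) x$seawater_influenced else 0
  stats::setNames(v, x$sample_id)
}

#' Summarize contamination against fraction cutoffs
#'
#' For each cutoff, counts the samples whose contamination fraction is
#' strictly above it and those at or below it (both tails reported). Useful
#' for statements like "22 of 60 samples exceed 20% contamination".
#'
#' @param report A `screening_report`.
#' @param cutoffs Fractions in `[0, 1]`; default `c(0.2, 0.5)`.
#' @param include_seawater See [contamination_fraction()].
#' @return Data frame with one row per cutoff: `cutoff`, `n_samples`,
#'   `n_above`, `frac_above`, `n_at_or_below`, `frac_at_or_below`.
#' @export
summarize_contamination <- function(report, cutoffs = c(0.2, 0.5),
                                    include_seawater = TRUE) {
  stopifnot(all(cutoffs >= 0), all(cutoffs <= 1))
  load <- contamination_fraction(report, include_seawater)
  n <- length(load)
  out <- data.frame(cutoff = cutoffs,
                    n_samples = n,
                    n_above = vapply(cutoffs, function(c) sum(load > c), 0L),
                    stringsAsFactors = FALSE)
  out$frac_above <- if (n) out$n_above / n else 0
  out$n_at_or_below <- n - out$n_above
  out$frac_at_or_below <- if (n) out$n_at_or_below / n else 0
  out
}

#' Write a screening report's three output tables
#'
#' @param report A `screening_report`.
#' @param outdir Output directory (created if needed). Writes
#'   `screening_per_sample.tsv` (one row per sample, label fractions +
#'   coverage), `screening_detail.tsv` (long format for stacked-bar plotting)
#'   and `screening_summary.tsv` (threshold summary).
#' @param cutoffs Passed to [summarize_contamination()].
#' @return Named character vector of the three paths, invisibly.
#' @export
write_screening_report <- function(report, outdir, cutoffs = c(0.2, 0.5)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(per_sample = file.path(outdir, "screening_per_sample.tsv"),
             detail = file.path(outdir, "screening_detail.tsv"),
             summary = file.path(outdir, "screening_summary.tsv"))
  utils::write.table(report$per_sample, paths["per_sample"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$detail, paths["detail"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summarize_contamination(report, cutoffs),
                     paths["summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
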
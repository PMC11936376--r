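# On-disk dialects and validation for the three input tables.
#
# A feature table is an integer matrix of ASV read counts (features x samples),
# a taxonomy table maps each ASV to a ranked lineage (domain..genus, NA for
# missing ranks), and a sample manifest assigns each sample a control role.

#' Lineage ranks used throughout the package
#'
#' Ordered vector of the six ranks a lineage may carry. Taxonomic assignment of
#' short amplicons below the genus level is unreliable, so species is not
#' modelled.
#'
#' @return Character vector `c("domain", "phylum", "class", "order", "family",
#'   "genus")`.
#' @export
lineage_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

#' Sample roles recognised in a manifest
#'
#' The three control groups mirror the provenance of negative controls in
#' scientific ocean drilling surveys: `control_I` covers drilling-associated
#' sources (equipment swabs, lubricants, paints), `control_II` laboratory
#' sources (extraction/PCR blanks, lab air), and `control_III` seawater and
#' drilling fluids. Everything to be screened is `query`.
#'
#' @return Character vector of the four legal roles.
#' @export
sample_roles <- function() {
  c("control_I", "control_II", "control_III", "query")
}

#' Reserved label for reads without an assignment at the aggregation rank
#'
#' The label is namespaced with underscores so that it can never collide with a
#' taxonomy label coming from a reference database such as Silva.
#'
#' @return A single string.
#' @export
unassigned_label <- function() {
  "__unassigned__"
}

.feature_table_dialects <- c("tsv_features_by_samples", "tsv_samples_by_features")
.taxonomy_dialects <- c("silva_prefixed_string", "rank_columns")

#' Construct and validate a feature table
#'
#' @param counts A matrix (or object coercible to one) of read counts with
#'   feature ids as row names and sample ids as column names.
#' @return An integer matrix, validated: all counts are non-negative integers
#'   and ids are unique. Zero-read samples are permitted (blanks routinely
#'   yield no reads) and flagged later by [validate_bundle()].
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  # empty margins legitimately carry NULL dimnames (R normalizes them away)
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0)) {
    stop("feature table needs feature ids as row names and sample ids as column names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("feature table counts must be numeric with no missing values")
  }
  if (any(counts < 0)) stop("feature table contains negative counts")
  if (any(counts != trunc(counts))) stop("feature table contains non-integer counts")
  storage.mode(counts) <- "integer"
  counts
}

#' Read a feature table from TSV
#'
#' @param path Path to a tab-separated file. In the default dialect the first
#'   column is `feature_id` and the remaining columns are sample ids; the
#'   transposed dialect (`tsv_samples_by_features`, first column `sample_id`)
#'   must be requested explicitly -- it is never auto-detected, because silent
#'   transposition of a square-ish table is invisible data corruption.
#' @param dialect One of `"tsv_features_by_samples"` (default) or
#'   `"tsv_samples_by_features"`.
#' @return A validated integer matrix, features x samples.
#' @export
read_feature_table <- function(path, dialect = "tsv_features_by_samples") {
  dialect <- match.arg(dialect, .feature_table_dialects)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  id_col <- if (dialect == "tsv_features_by_samples") "feature_id" else "sample_id"
  if (ncol(df) < 2 || names(df)[1] != id_col) {
    stop("malformed header at line 1 of ", path, ": first column must be '", id_col, "'")
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cell in ", path)
  rownames(m) <- ids
  if (dialect == "tsv_samples_by_features") m <- t(m)
  feature_table(m)
}

#' Write a feature table as TSV
#'
#' Writing then re-reading a table reproduces it exactly, and the write is
#' byte-stable: writing a freshly read file reproduces its bytes.
#'
#' @param table Feature table matrix (see [feature_table()]).
#' @param path Output path.
#' @param dialect See [read_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, dialect = "tsv_features_by_samples") {
  dialect <- match.arg(dialect, .feature_table_dialects)
  m <- feature_table(table)
  if (dialect == "tsv_samples_by_features") m <- t(m)
  id_col <- if (dialect == "tsv_features_by_samples") "feature_id" else "sample_id"
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.strip_rank_prefix <- function(x) {
  sub("^[dpcofgs]__", "", x)
}

#' Parse a single prefixed lineage string
#'
#' @param x A Silva-style lineage string such as
#'   `"d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Burkholderiales;f__;g__"`.
#'   Rank prefixes are optional and stripped; empty fields and the literal
#'   `"na"`/`"NA"` become missing (`NA`). Labels are otherwise kept verbatim --
#'   strings like `"SAR11 clade"` or `"Subgroup 2"` are legal order labels.
#' @param feature_id Used in error messages only.
#' @return Named character vector over [lineage_ranks()]; missing ranks are `NA`.
#' @export
parse_lineage <- function(x, feature_id = "<feature>") {
  ranks <- lineage_ranks()
  parts <- strsplit(as.character(x), ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (length(parts) > length(ranks)) {
    stop("feature ", feature_id, ": lineage has ", length(parts),
         " ranks, at most ", length(ranks), " are supported")
  }
  parts <- .strip_rank_prefix(parts)
  parts[parts == "" | parts %in% c("na", "NA")] <- NA_character_
  out <- rep(NA_character_, length(ranks))
  out[seq_along(parts)] <- parts
  names(out) <- ranks
  out
}

#' Read a taxonomy table
#'
#' @param path TSV file. Dialect `"silva_prefixed_string"` expects two columns,
#'   `feature_id` and a lineage string parsed by [parse_lineage()];
#'   `"rank_columns"` expects `feature_id` plus one column per rank in
#'   [lineage_ranks()] (cells `""`/`"na"`/`"NA"` are missing).
#' @param dialect One of the two dialect names.
#' @return A data frame with columns `feature_id` plus the six ranks; missing
#'   ranks are `NA`, never empty strings.
#' @export
read_taxonomy <- function(path, dialect = "silva_prefixed_string") {
  dialect <- match.arg(dialect, .taxonomy_dialects)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  ranks <- lineage_ranks()
  if (names(df)[1] != "feature_id") {
    stop("malformed header at line 1 of ", path, ": first column must be 'feature_id'")
  }
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature ids in taxonomy: ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
  }
  if (dialect == "silva_prefixed_string") {
    if (ncol(df) != 2) stop(path, ": expected columns feature_id, lineage")
    lin <- t(vapply(seq_len(nrow(df)),
                    function(i) parse_lineage(df[[2]][i], df$feature_id[i]),
                    character(length(ranks))))
    out <- data.frame(feature_id = df$feature_id, lin,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    if (!all(ranks %in% names(df))) {
      stop(path, ": rank_columns dialect needs columns ",
           paste(ranks, collapse = ", "))
    }
    out <- df[, c("feature_id", ranks)]
    for (r in ranks) {
      v <- trimws(out[[r]])
      v[v == "" | v %in% c("na", "NA")] <- NA_character_
      out[[r]] <- v
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a taxonomy table as a rank-column TSV
#'
#' @param taxonomy Taxonomy data frame as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- taxonomy[, c("feature_id", lineage_ranks())]
  for (r in lineage_ranks()) df[[r]][is.na(df[[r]])] <- "na"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' @param path TSV with columns `sample_id`, `role`, `source`. `role` must be
#'   one of [sample_roles()]; `source` is a free-text provenance label such as
#'   "PCR blank" or "drilling fluid".
#' @return A data frame with those three columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("sample_id", "role", "source")
  if (!all(need %in% names(df))) {
    stop(path, ": manifest needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop(path, ": manifest contains no samples")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$role), sample_roles())
  if (length(bad)) {
    stop("unknown role(s) ", paste(bad, collapse = ", "),
         "; legal values: ", paste(sample_roles(), collapse = ", "))
  }
  df[, need]
}

#' Write a sample manifest as TSV
#'
#' @param manifest Manifest data frame (columns `sample_id`, `role`, `source`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("sample_id", "role", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validate a feature table, taxonomy and manifest
#'
#' Checks that every sample in the table appears in the manifest (and vice
#' versa) and that every feature has a taxonomy entry. Zero-read samples are
#' reported as warnings, not errors: extraction and PCR blanks legitimately
#' yield no reads and are kept in the sample accounting.
#'
#' @param table Feature table matrix.
#' @param taxonomy Taxonomy data frame.
#' @param manifest Manifest data frame.
#' @return A `bundle_validation` list with character vectors `errors` and
#'   `warnings` plus `zero_read_samples`; `valid` is `TRUE` when there are no
#'   errors.
#' @export
validate_bundle <- function(table, taxonomy, manifest) {
  table <- feature_table(table)
  errors <- character()
  warnings <- character()

  zero <- colnames(table)[colSums(table) == 0]
  if (length(zero)) {
    warnings <- c(warnings, paste0("zero-read sample(s): ", paste(zero, collapse = ", ")))
  }
  missing_tax <- setdiff(rownames(table), taxonomy$feature_id)
  if (length(missing_tax)) {
    errors <- c(errors, paste0("feature(s) lacking taxonomy: ",
                               paste(missing_tax, collapse = ", ")))
  }
  not_in_manifest <- setdiff(colnames(table), manifest$sample_id)
  if (length(not_in_manifest)) {
    errors <- c(errors, paste0("sample(s) missing from manifest: ",
                               paste(not_in_manifest, collapse = ", ")))
  }
  not_in_table <- setdiff(manifest$sample_id, colnames(table))
  if (length(not_in_table)) {
    errors <- c(errors, paste0("manifest sample(s) absent from table: ",
                               paste(not_in_table, collapse = ", ")))
  }
  structure(list(errors = errors, warnings = warnings,
                 zero_read_samples = zero,
                 valid = length(errors) == 0L),
            class = "bundle_validation")
}

#' @export
print.bundle_validation <- function(x, ...) {
  cat("Bundle validation:", if (x$valid) "OK" else "FAILED", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
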
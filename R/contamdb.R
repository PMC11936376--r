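# Building the two-part contaminant database: the "laboratory" order list from
# drilling-associated + laboratory controls (groups I and II, pooled) and the
# "seawater" list from seawater/drilling-fluid controls (group III), each the
# top-k most abundant orders subject to a minimum pooled read fraction.

DB_SCHEMA_VERSION <- "1.0"

#' Screening configuration
#'
#' Houses the pipeline's constants. Defaults follow the published screening
#' practice for drilling-survey controls: order-level aggregation, the 30 most
#' abundant orders per control pool, a 1% minimum pooled read fraction for
#' database membership, ASV filters of >= 5 total reads and presence in >= 2
#' samples, and a 1% per-sample relative-abundance floor below which an
#' order's reads are binned as below-threshold rather than classified.
#'
#' @param rank Taxonomic rank for aggregation (default `"order"`).
#' @param top_k Number of top orders retained per control pool (default 30).
#' @param min_pooled_fraction Minimum pooled read fraction for database
#'   membership (default 0.01).
#' @param min_reads Minimum total reads per ASV (default 5).
#' @param min_occurrence Minimum number of samples an ASV must appear in
#'   (default 2).
#' @param per_sample_threshold Per-sample order-level relative-abundance floor
#'   applied during screening (default 0.01).
#' @return A `screening_config` list.
#' @export
screening_config <- function(rank = "order", top_k = 30,
                             min_pooled_fraction = 0.01, min_reads = 5,
                             min_occurrence = 2, per_sample_threshold = 0.01) {
  rank <- match.arg(rank, lineage_ranks())
  stopifnot(top_k >= 0, top_k == trunc(top_k),
            min_reads >= 0, min_reads == trunc(min_reads),
            min_occurrence >= 0, min_occurrence == trunc(min_occurrence),
            min_pooled_fraction >= 0, min_pooled_fraction <= 1,
            per_sample_threshold >= 0, per_sample_threshold <= 1)
  structure(list(rank = rank, top_k = as.integer(top_k),
                 min_pooled_fraction = min_pooled_fraction,
                 min_reads = as.integer(min_reads),
                 min_occurrence = as.integer(min_occurrence),
                 per_sample_threshold = per_sample_threshold),
            class = "screening_config")
}

#' Rank orders by pooled read fraction over a set of control samples
#'
#' The ranking statistic is the pooled read fraction: reads of the order summed
#' over the subset, divided by total reads over the subset (the denominator
#' includes unassigned reads). The unassigned bucket itself is excluded from
#' the ranking. Ties are broken lexicographically by label.
#'
#' @param agg Aggregated count matrix from [aggregate_to_rank()].
#' @param sample_subset Sample ids to pool; must be nonempty with nonzero total
#'   reads after zero-read exclusion.
#' @return Data frame with columns `order`, `pooled_reads`, `pooled_fraction`,
#'   `n_samples` (control samples containing the order), `rank` (1-based
#'   position), sorted by decreasing fraction.
#' @export
pooled_order_fractions <- function(agg, sample_subset = colnames(agg)) {
  missing <- setdiff(sample_subset, colnames(agg))
  if (length(missing)) {
    stop("sample(s) not in table: ", paste(missing, collapse = ", "))
  }
  sub <- agg[, sample_subset, drop = FALSE]
  sub <- sub[, colSums(sub) > 0, drop = FALSE]
  if (ncol(sub) == 0) stop("empty sample subset (after zero-read exclusion)")
  total <- sum(as.numeric(sub))
  keep <- setdiff(rownames(sub), unassigned_label())
  reads <- rowSums(sub[keep, , drop = FALSE])
  occ <- rowSums(sub[keep, , drop = FALSE] >= 1)
  ord <- order(-reads, keep, method = "radix")
  out <- data.frame(order = keep[ord],
                    pooled_reads = as.numeric(reads[ord]),
                    pooled_fraction = as.numeric(reads[ord]) / total,
                    n_samples = as.integer(occ[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the database members from a pooled ranking
#'
#' Takes the first `top_k` records; records tied (equal pooled fraction) with
#' the record at rank `top_k` are retained as well, then anything below
#' `min_pooled_fraction` is dropped.
#'
#' @param ranked Output of [pooled_order_fractions()].
#' @param top_k,min_pooled_fraction See [screening_config()].
#' @return The surviving subset of `ranked`, in rank order.
#' @export
select_top_orders <- function(ranked, top_k = 30, min_pooled_fraction = 0.01) {
  if (nrow(ranked) == 0) return(ranked)
  if (nrow(ranked) > top_k) {
    if (top_k == 0) {
      ranked <- ranked[0, , drop = FALSE]
    } else {
      cut <- ranked$pooled_fraction[top_k]
      ranked <- ranked[ranked$pooled_fraction >= cut, , drop = FALSE]
    }
  }
  out <- ranked[ranked$pooled_fraction >= min_pooled_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

.db_structure <- function(laboratory, seawater, rank, config = NULL,
                          provenance = list()) {
  ub <- sort(intersect(laboratory$order, seawater$order), method = "radix")
  structure(list(schema_version = DB_SCHEMA_VERSION,
                 rank = rank,
                 config = config,
                 laboratory = laboratory,
                 seawater = seawater,
                 ubiquitous = ub,
                 provenance = provenance),
            class = "contaminant_database")
}

#' Build the contaminant database from control samples
#'
#' Control groups I (drilling-associated) and II (laboratory blanks/air) are
#' pooled into the single "laboratory" list; group III (seawater and drilling
#' fluids) gives the "seawater" list. Within each pool, the ASV filters
#' (`min_reads`, `min_occurrence`) are applied across that pool's samples,
#' counts are rolled up to `config$rank`, and the top-k orders above
#' `min_pooled_fraction` are retained. Orders on both lists are flagged as
#' ubiquitous. Building is deterministic: identical inputs and config give a
#' byte-identical serialized database.
#'
#' @param table Feature table matrix.
#' @param taxonomy Taxonomy data frame.
#' @param manifest Sample manifest; must contain at least one sample in groups
#'   I or II and at least one in group III.
#' @param config A [screening_config()].
#' @return A `contaminant_database` object.
#' @export
build_database <- function(table, taxonomy, manifest,
                           config = screening_config()) {
  table <- feature_table(table)
  val <- validate_bundle(table, taxonomy, manifest)
  if (!val$valid) stop("invalid bundle: ", paste(val$errors, collapse = "; "))

  pools <- list(
    laboratory = manifest$sample_id[manifest$role %in% c("control_I", "control_II")],
    seawater = manifest$sample_id[manifest$role == "control_III"]
  )
  groups_needed <- c(laboratory = "control_I/control_II", seawater = "control_III")
  sets <- lapply(names(pools), function(pool) {
    ids <- intersect(pools[[pool]], colnames(table))
    ids <- ids[colSums(table[, ids, drop = FALSE]) > 0]
    if (length(ids) == 0) {
      stop("no usable control samples for the ", pool, " pool (role ",
           groups_needed[[pool]], ")")
    }
    sub <- table[, ids, drop = FALSE]
    sub <- filter_min_total_reads(sub, config$min_reads)
    sub <- filter_min_occurrence(sub, config$min_occurrence)
    agg <- aggregate_to_rank(sub, taxonomy, config$rank)
    ranked <- pooled_order_fractions(agg, ids)
    sel <- select_top_orders(ranked, config$top_k, config$min_pooled_fraction)
    list(records = sel, n_samples = length(ids))
  })
  names(sets) <- names(pools)

  prov <- list(
    builder = paste0("contamscreen ", as.character(utils::packageVersion("contamscreen"))),
    n_laboratory_controls = sets$laboratory$n_samples,
    n_seawater_controls = sets$seawater$n_samples,
    input_digests = list(table = .md5_of(table),
                         taxonomy = .md5_of(taxonomy),
                         manifest = .md5_of(manifest)),
    per_group_samples = list(
      control_I = manifest$sample_id[manifest$role == "control_I"],
      control_II = manifest$sample_id[manifest$role == "control_II"],
      control_III = manifest$sample_id[manifest$role == "control_III"]
    )
  )
  .db_structure(sets$laboratory$records, sets$seawater$records,
                rank = config$rank, config = unclass(config), provenance = prov)
}

#' Construct a database directly from order label sets
#'
#' Used for planted-truth databases in simulations and for transcribed
#' reference lists where pooled fractions are unknown (`NA`).
#'
#' @param laboratory,seawater Character vectors of order labels.
#' @param rank Taxonomic rank of the labels.
#' @param provenance Optional provenance list.
#' @return A `contaminant_database` object.
#' @export
database_from_orders <- function(laboratory, seawater, rank = "order",
                                 provenance = list()) {
  mk <- function(labels) {
    data.frame(order = as.character(labels),
               pooled_reads = NA_real_, pooled_fraction = NA_real_,
               n_samples = NA_integer_, rank = seq_along(labels),
               stringsAsFactors = FALSE)
  }
  .db_structure(mk(laboratory), mk(seawater), rank = rank,
                provenance = provenance)
}

#' @export
print.contaminant_database <- function(x, ...) {
  cat("Contaminant database (rank:", x$rank, ")\n")
  cat("  laboratory orders:", nrow(x$laboratory), "\n")
  cat("  seawater orders:  ", nrow(x$seawater), "\n")
  cat("  ubiquitous:       ", length(x$ubiquitous), "\n")
  invisible(x)
}

.records_to_json_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    list(order = df$order[i],
         pooled_reads = df$pooled_reads[i],
         pooled_fraction = df$pooled_fraction[i],
         n_samples = df$n_samples[i],
         rank = df$rank[i])
  })
}

.records_from_json <- function(lst) {
  if (length(lst) == 0) {
    return(data.frame(order = character(), pooled_reads = numeric(),
                      pooled_fraction = numeric(), n_samples = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    order = vapply(lst, function(r) as.character(r$order), ""),
    pooled_reads = vapply(lst, function(r) if (is.null(r$pooled_reads)) NA_real_ else as.numeric(r$pooled_reads), 0),
    pooled_fraction = vapply(lst, function(r) if (is.null(r$pooled_fraction)) NA_real_ else as.numeric(r$pooled_fraction), 0),
    n_samples = vapply(lst, function(r) if (is.null(r$n_samples)) NA_integer_ else as.integer(r$n_samples), 0L),
    rank = vapply(lst, function(r) as.integer(r$rank), 0L),
    stringsAsFactors = FALSE)
}

#' Serialize a contaminant database to JSON
#'
#' Keys are written in a fixed order and numbers at full precision, so the
#' file is byte-reproducible for identical inputs. Timestamps are deliberately
#' kept out of the database (they belong in the CLI run manifest).
#'
#' @param db A `contaminant_database`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "contaminant_database"))
  payload <- list(schema_version = db$schema_version,
                  rank = db$rank,
                  config = db$config,
                  laboratory = .records_to_json_list(db$laboratory),
                  seawater = .records_to_json_list(db$seawater),
                  ubiquitous = db$ubiquitous,
                  provenance = db$provenance)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a contaminant database from JSON
#'
#' The ubiquitous set is recomputed as the intersection of the two order lists
#' and checked against the stored value; a mismatch is an integrity error (the
#' file was edited or truncated).
#'
#' @param path Path to a database JSON file.
#' @return A `contaminant_database`.
#' @export
read_database <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("corrupt database file ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(raw$schema_version) || !identical(as.character(raw$schema_version),
                                                DB_SCHEMA_VERSION)) {
    stop("unsupported database schema version in ", path)
  }
  lab <- .records_from_json(raw$laboratory)
  sw <- .records_from_json(raw$seawater)
  stored_ub <- sort(vapply(raw$ubiquitous, as.character, "", USE.NAMES = FALSE),
                    method = "radix")
  db <- .db_structure(lab, sw, rank = as.character(raw$rank),
                      config = raw$config, provenance = raw$provenance)
  if (!identical(db$ubiquitous, stored_ub)) {
    stop("integrity error in ", path, ": stored ubiquitous set does not equal ",
         "the intersection of the laboratory and seawater order lists")
  }
  db
}

#' The packaged reference contaminant database
#'
#' A transcription of the most common contaminant orders compiled from
#' published 16S rRNA surveys of scientific ocean drilling contamination
#' controls: a laboratory list (drilling equipment, lubricants, extraction and
#' PCR blanks, lab air) and a seawater list (seawater and drilling fluids).
#' It allows screening when no control samples of one's own are available; it
#' complements, and does not replace, study-specific controls.
#'
#' @return A `contaminant_database` at the order rank.
#' @export
reference_database <- function() {
  path <- system.file("extdata", "reference_contaminant_db.json",
                      package = "contamscreen", mustWork = TRUE)
  read_database(path)
}
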
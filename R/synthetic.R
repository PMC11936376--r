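# Dirichlet-multinomial community simulator with ground truth.
#
# Each sample draws order proportions from a Dirichlet centred on its role's
# pool weights, mixes the laboratory / seawater / endemic pools by planted
# fractions, expands orders into ASVs with geometric within-order weights
# (steeply skewed for dominance-flagged orders, reproducing the
# many-reads-few-ASVs pattern of overamplified taxa such as Burkholderiales),
# and draws counts multinomially at a log-uniform depth. Every sample has its
# own RNG stream keyed on its id, so adding samples never perturbs existing
# ones and a seed fully determines the output.

.pool_frame <- function(x, pool) {
  need <- c("order", "weight", "n_asvs", "dominant")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(pool, " pool must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (any(x$weight < 0) || !any(x$weight > 0)) {
    stop(pool, " pool needs non-negative weights with at least one positive")
  }
  if (any(x$n_asvs < 1)) stop(pool, " pool: n_asvs must be >= 1")
  x[need]
}

#' Describe the three order pools of a simulated community
#'
#' @param laboratory,seawater,endemic Data frames with columns `order` (label),
#'   `weight` (non-negative Dirichlet base weight), `n_asvs` (ASVs per order)
#'   and `dominant` (logical; reads concentrate in few ASVs).
#' @param skew Geometric decay ratio in `(0, 1]` for ASV weights within
#'   dominance-flagged orders (`1` = uniform; smaller = steeper). Non-flagged
#'   orders use uniform ASV weights.
#' @return A `community_spec` list.
#' @export
community_spec <- function(laboratory, seawater, endemic, skew = 0.3) {
  stopifnot(skew > 0, skew <= 1)
  structure(list(laboratory = .pool_frame(laboratory, "laboratory"),
                 seawater = .pool_frame(seawater, "seawater"),
                 endemic = .pool_frame(endemic, "endemic"),
                 skew = skew),
            class = "community_spec")
}

.order_frame <- function(orders, weight = 1, n_asvs = 5, dominant = FALSE) {
  data.frame(order = orders, weight = weight, n_asvs = n_asvs,
             dominant = dominant, stringsAsFactors = FALSE)
}

#' Default community: reference contaminant orders plus invented endemics
#'
#' The laboratory pool uses the packaged reference database's laboratory
#' orders with Burkholderiales given a 12x base weight and a dominance flag
#' (it dominates read counts, not ASV counts, in real low-biomass controls);
#' the seawater pool uses the reference seawater orders with even weights
#' (marine communities are comparatively even); the endemic pool is ten
#' synthetic order labels that exist in no reference list.
#'
#' @param skew Passed to [community_spec()].
#' @return A `community_spec`.
#' @export
default_community_spec <- function(skew = 0.3) {
  ref <- reference_database()
  lab <- .order_frame(ref$laboratory$order)
  dom <- lab$order == "Burkholderiales"
  lab$weight[dom] <- 12
  lab$n_asvs[dom] <- 20
  lab$dominant[dom] <- TRUE
  sw <- .order_frame(ref$seawater$order)
  end <- .order_frame(sprintf("Endemicales_%02d", 1:10))
  community_spec(lab, sw, end, skew = skew)
}

#' Disjoint-pool community for recovery experiments
#'
#' Synthetic order labels with no overlap between pools, so the true
#' laboratory read fraction of a sample is exactly the fraction of reads in
#' laboratory-pool orders and recovery of the planted contaminant load can be
#' measured without label ambiguity.
#'
#' @param n_laboratory,n_seawater,n_endemic Orders per pool.
#' @param n_asvs ASVs per order.
#' @param skew Passed to [community_spec()].
#' @return A `community_spec`.
#' @export
disjoint_community_spec <- function(n_laboratory = 5, n_seawater = 5,
                                    n_endemic = 8, n_asvs = 6, skew = 0.5) {
  community_spec(
    .order_frame(sprintf("SimLabOrder_%02d", seq_len(n_laboratory)), n_asvs = n_asvs),
    .order_frame(sprintf("SimSeaOrder_%02d", seq_len(n_seawater)), n_asvs = n_asvs),
    .order_frame(sprintf("SimEndOrder_%02d", seq_len(n_endemic)), n_asvs = n_asvs),
    skew = skew)
}

#' Simulation configuration
#'
#' @param n_control_I,n_control_II,n_control_III,n_query Samples per role.
#' @param n_blanks Extra laboratory blanks emitted as all-zero columns
#'   (role `control_II`), mimicking extraction/PCR blanks that yield no ASVs.
#' @param depth_range Two positive numbers; per-sample read depths are drawn
#'   log-uniformly over this range (default `c(1e3, 4e5)`, echoing the wide
#'   depth spread of real control sets).
#' @param concentration Total Dirichlet concentration for order proportions
#'   within a pool (larger = less sample-to-sample variability; default 50).
#' @param contaminant_load Planted laboratory-pool read fraction per query
#'   sample (default 0.3).
#' @param seawater_load Planted seawater-pool fraction per query (default 0.1);
#'   `contaminant_load + seawater_load` must be <= 1, the remainder is endemic.
#' @param seed Integer; fully determines the simulated bundle.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_control_I = 8, n_control_II = 8,
                              n_control_III = 8, n_query = 6, n_blanks = 3,
                              depth_range = c(1e3, 4e5), concentration = 50,
                              contaminant_load = 0.3, seawater_load = 0.1,
                              seed = 1) {
  stopifnot(n_control_I >= 0, n_control_II >= 0, n_control_III >= 0,
            n_query >= 0, n_blanks >= 0,
            length(depth_range) == 2, all(depth_range >= 1),
            depth_range[1] <= depth_range[2], concentration > 0,
            contaminant_load >= 0, seawater_load >= 0)
  if (contaminant_load + seawater_load > 1) {
    stop("infeasible planted fractions: contaminant_load + seawater_load > 1")
  }
  structure(list(n_control_I = as.integer(n_control_I),
                 n_control_II = as.integer(n_control_II),
                 n_control_III = as.integer(n_control_III),
                 n_query = as.integer(n_query),
                 n_blanks = as.integer(n_blanks),
                 depth_range = as.numeric(depth_range),
                 concentration = concentration,
                 contaminant_load = contaminant_load,
                 seawater_load = seawater_load,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic 31-bit hash of a string, for per-sample RNG streams.
.string_hash <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

.with_stream <- function(seed, id, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + .string_hash(id)) %% 2147483647L)
  force(expr)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha  # degenerate gamma draw: fall back to the mean
  g / sum(g)
}

# ASV registry: one row per (pool, order, asv index); ids are deterministic.
.asv_registry <- function(spec) {
  out <- lapply(c("laboratory", "seawater", "endemic"), function(pool) {
    p <- spec[[pool]]
    do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
      m <- p$n_asvs[i]
      ratio <- if (p$dominant[i]) spec$skew else 1
      w <- ratio^(seq_len(m) - 1)
      slug <- gsub("[^A-Za-z0-9]+", "_", p$order[i])
      data.frame(feature_id = sprintf("asv_%s_%s_%03d", substr(pool, 1, 3),
                                      slug, seq_len(m)),
                 pool = pool, order = p$order[i],
                 asv_weight = w / sum(w), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

.sample_counts <- function(spec, registry, mix, depth, concentration) {
  probs <- numeric(nrow(registry))
  for (pool in names(mix)) {
    if (mix[[pool]] <= 0) next
    p <- spec[[pool]]
    alpha <- concentration * p$weight / sum(p$weight)
    props <- .rdirichlet1(alpha)
    idx <- registry$pool == pool
    ord_prop <- stats::setNames(props, p$order)
    probs[idx] <- probs[idx] +
      mix[[pool]] * ord_prop[registry$order[idx]] * registry$asv_weight[idx]
  }
  as.integer(stats::rmultinom(1, size = depth, prob = probs))
}

#' Simulate a full screening bundle with ground truth
#'
#' Emits a feature table, taxonomy, manifest and a truth record: control
#' samples are pure draws from their pool (groups I and II from the laboratory
#' pool, group III from the seawater pool), queries are planted mixtures of
#' laboratory + seawater + endemic reads, and blanks are all-zero columns.
#'
#' @param spec A [community_spec()].
#' @param config A [simulation_config()].
#' @return A `sim_bundle` list with `table`, `taxonomy`, `manifest` and
#'   `truth` (`samples`: per-sample planted fractions; `database`: the planted
#'   laboratory and seawater order sets; `asv_source`: per-ASV pool of origin).
#' @export
simulate_bundle <- function(spec = default_community_spec(),
                            config = simulation_config()) {
  stopifnot(inherits(spec, "community_spec"),
            inherits(config, "simulation_config"))
  registry <- .asv_registry(spec)

  roles <- c(rep("control_I", config$n_control_I),
             rep("control_II", config$n_control_II),
             rep("control_III", config$n_control_III),
             rep("query", config$n_query),
             rep("control_II", config$n_blanks))
  ids <- c(sprintf("ctrlI_%02d", seq_len(config$n_control_I)),
           sprintf("ctrlII_%02d", seq_len(config$n_control_II)),
           sprintf("ctrlIII_%02d", seq_len(config$n_control_III)),
           sprintf("query_%02d", seq_len(config$n_query)),
           sprintf("blank_%02d", seq_len(config$n_blanks)))
  sources <- c(rep("drilling equipment swab", config$n_control_I),
               rep("DNA extraction blank", config$n_control_II),
               rep("seawater", config$n_control_III),
               rep("sediment core", config$n_query),
               rep("PCR blank", config$n_blanks))
  is_blank <- grepl("^blank_", ids)

  mixes <- list(control_I = c(laboratory = 1, seawater = 0, endemic = 0),
                control_II = c(laboratory = 1, seawater = 0, endemic = 0),
                control_III = c(laboratory = 0, seawater = 1, endemic = 0),
                query = c(laboratory = config$contaminant_load,
                          seawater = config$seawater_load,
                          endemic = 1 - config$contaminant_load -
                            config$seawater_load))

  counts <- matrix(0L, nrow = nrow(registry), ncol = length(ids),
                   dimnames = list(registry$feature_id, ids))
  lr <- log(config$depth_range)
  for (i in seq_along(ids)) {
    if (is_blank[i]) next
    counts[, i] <- .with_stream(config$seed, ids[i], {
      depth <- round(exp(stats::runif(1, lr[1], lr[2])))
      .sample_counts(spec, registry, mixes[[roles[i]]], depth,
                     config$concentration)
    })
  }

  taxonomy <- data.frame(feature_id = registry$feature_id,
                         domain = "Bacteria", phylum = NA_character_,
                         class = NA_character_, order = registry$order,
                         family = NA_character_, genus = NA_character_,
                         stringsAsFactors = FALSE)
  manifest <- data.frame(sample_id = ids, role = roles, source = sources,
                         stringsAsFactors = FALSE)
  truth_samples <- data.frame(
    sample_id = ids, role = roles,
    true_laboratory = vapply(roles, function(r) mixes[[r]][["laboratory"]], 0),
    true_seawater = vapply(roles, function(r) mixes[[r]][["seawater"]], 0),
    true_endemic = vapply(roles, function(r) mixes[[r]][["endemic"]], 0),
    stringsAsFactors = FALSE)
  truth_samples[is_blank, c("true_laboratory", "true_seawater", "true_endemic")] <- NA
  rownames(truth_samples) <- NULL

  structure(list(
    table = feature_table(counts),
    taxonomy = taxonomy,
    manifest = manifest,
    truth = list(
      samples = truth_samples,
      database = list(
        laboratory = sort(unique(spec$laboratory$order), method = "radix"),
        seawater = sort(unique(spec$seawater$order), method = "radix")),
      asv_source = registry[, c("feature_id", "pool", "order")])),
    class = "sim_bundle")
}

#' Write a simulated bundle to disk
#'
#' @param bundle A `sim_bundle`.
#' @param outdir Output directory (created if needed). Writes `table.tsv`,
#'   `taxonomy.tsv`, `manifest.tsv`, `truth.tsv` (per-sample planted
#'   fractions) and `planted_db.json` (the planted order sets as a database).
#' @return Named character vector of paths, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(outdir, "table.tsv"),
             taxonomy = file.path(outdir, "taxonomy.tsv"),
             manifest = file.path(outdir, "manifest.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             planted_db = file.path(outdir, "planted_db.json"))
  write_feature_table(bundle$table, paths["table"])
  write_taxonomy(bundle$taxonomy, paths["taxonomy"])
  write_manifest(bundle$manifest, paths["manifest"])
  utils::write.table(bundle$truth$samples, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_database(database_from_orders(bundle$truth$database$laboratory,
                                      bundle$truth$database$seawater,
                                      provenance = list(note = "planted simulation truth")),
                 paths["planted_db"])
  invisible(paths)
}

#' Compare a screening report with simulation truth
#'
#' @param truth Either a `sim_bundle`'s `truth` element or the per-sample
#'   truth data frame written by [write_bundle()].
#' @param report A `screening_report` (or its `per_sample` data frame) whose
#'   sample ids must exactly match the truth's screened query samples.
#' @param db Optional `contaminant_database` to score against the planted
#'   order sets (requires the full truth element).
#' @return A list: `per_sample` (absolute errors on the laboratory and
#'   seawater fractions), `mean_abs_error_laboratory`,
#'   `mean_abs_error_seawater`, and -- when `db` is given --
#'   `db_precision_laboratory`, `db_recall_laboratory`, `db_precision_seawater`,
#'   `db_recall_seawater`.
#' @export
evaluate_screening <- function(truth, report, db = NULL) {
  tdf <- if (is.data.frame(truth)) truth else truth$samples
  per <- if (inherits(report, "screening_report")) report$per_sample else report
  tq <- tdf[tdf$role == "query", , drop = FALSE]
  if (!setequal(per$sample_id, tq$sample_id) ||
      anyDuplicated(per$sample_id)) {
    stop("sample id mismatch between truth and report")
  }
  m <- match(per$sample_id, tq$sample_id)
  per_sample <- data.frame(
    sample_id = per$sample_id,
    true_laboratory = tq$true_laboratory[m],
    est_laboratory = per$potential_contaminant,
    abs_error_laboratory = abs(per$potential_contaminant - tq$true_laboratory[m]),
    true_seawater = tq$true_seawater[m],
    est_seawater = per$seawater_influenced,
    abs_error_seawater = abs(per$seawater_influenced - tq$true_seawater[m]),
    stringsAsFactors = FALSE)
  out <- list(per_sample = per_sample,
              mean_abs_error_laboratory = mean(per_sample$abs_error_laboratory),
              mean_abs_error_seawater = mean(per_sample$abs_error_seawater))
  if (!is.null(db)) {
    if (is.data.frame(truth)) stop("database scoring needs the full truth record")
    score <- function(est, planted) {
      tp <- length(intersect(est, planted))
      c(precision = if (length(est)) tp / length(est) else 1,
        recall = if (length(planted)) tp / length(planted) else 1)
    }
    lab <- score(db$laboratory$order, truth$database$laboratory)
    sw <- score(db$seawater$order, truth$database$seawater)
    out$db_precision_laboratory <- lab[["precision"]]
    out$db_recall_laboratory <- lab[["recall"]]
    out$db_precision_seawater <- sw[["precision"]]
    out$db_recall_seawater <- sw[["recall"]]
  }
  out
}
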
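test_that("order labelling follows the documented precedence", {
  db <- toy_db()
  cfg <- screening_config()
  expect_identical(label_order("Burkholderiales", 0.40, db, cfg),
                   "potential_contaminant")  # ubiquitous: laboratory wins
  expect_identical(label_order("Nitrosopumilales", 0.10, db, cfg),
                   "seawater_influenced")
  expect_identical(label_order("Deepsealesales", 0.30, db, cfg), "endemic")
  expect_identical(label_order("Burkholderiales", 0.005, db, cfg),
                   "below_threshold")
  expect_identical(label_order(unassigned_label(), 0.5, db, cfg), "unassigned")
  # with a zero threshold nothing is below it
  cfg0 <- screening_config(per_sample_threshold = 0)
  expect_identical(label_order("Burkholderiales", 0.005, db, cfg0),
                   "potential_contaminant")
})

test_that("the reference database labels canonical orders correctly", {
  ref <- reference_database()
  cfg <- screening_config()
  expect_identical(label_order("Burkholderiales", 0.40, ref, cfg),
                   "potential_contaminant")
  expect_identical(label_order("Nitrosopumilales", 0.10, ref, cfg),
                   "seawater_influenced")
})

# A query bundle with known composition: per sample 1000 reads split over
# orders with known labels against toy_db().
screen_fixture <- function() {
  tab <- feature_table(matrix(c(
    400L, 0L,     # Burkholderiales (lab+sw)
    100L, 0L,     # Nitrosopumilales (sw only)
    494L, 995L,   # Deepsealesales (endemic)
    6L,   0L,     # Rarissimales (endemic, 0.6% < threshold in q1)
    0L,   5L),    # unassigned (0.5% -- but unassigned has precedence)
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("a", 1:5), c("q1", "q2"))))
  tx <- data.frame(feature_id = paste0("a", 1:5), domain = "Bacteria",
                   phylum = NA, class = NA,
                   order = c("Burkholderiales", "Nitrosopumilales",
                             "Deepsealesales", "Rarissimales", NA),
                   family = NA, genus = NA, stringsAsFactors = FALSE)
  mf <- data.frame(sample_id = c("q1", "q2"), role = "query",
                   source = "sediment core", stringsAsFactors = FALSE)
  list(table = tab, taxonomy = tx, manifest = mf)
}

test_that("screening computes per-label fractions, coverage and conservation", {
  b <- screen_fixture()
  cfg <- screening_config(min_reads = 0, min_occurrence = 0)
  rep <- screen_samples(b$table, b$taxonomy, b$manifest, toy_db(), cfg)
  q1 <- rep$per_sample[rep$per_sample$sample_id == "q1", ]
  expect_equal(q1$potential_contaminant, 0.4)
  expect_equal(q1$seawater_influenced, 0.1)
  expect_equal(q1$endemic, 0.494)
  expect_equal(q1$below_threshold, 0.006)
  expect_equal(q1$unassigned, 0)
  expect_equal(q1$coverage, 0.5)

  # all-endemic sample: contaminant fraction 0, the rest sums to 1
  q2 <- rep$per_sample[rep$per_sample$sample_id == "q2", ]
  expect_equal(q2$potential_contaminant, 0)
  expect_equal(q2$endemic + q2$below_threshold + q2$unassigned, 1)
  expect_equal(q2$unassigned, 0.005)
  expect_equal(q2$coverage, 0)

  # conservation for every sample
  sums <- rowSums(rep$per_sample[, c("potential_contaminant",
                                     "seawater_influenced", "endemic",
                                     "below_threshold", "unassigned")])
  expect_true(all(abs(sums - 1) < 1e-9))
  # coverage ignores the threshold, so it dominates the labelled contamination
  expect_true(all(rep$per_sample$coverage + 1e-12 >=
                    rep$per_sample$potential_contaminant +
                    rep$per_sample$seawater_influenced))
})

test_that("screening conserves label fractions and is permutation-invariant on random inputs", {
  set.seed(42)
  tab <- random_table(80, 10, seed = 77, lambda = 30)
  tx <- random_taxonomy(rownames(tab), 177,
                        orders = c("Burkholderiales", "Nitrosopumilales",
                                   "OrderA", "OrderB", "OrderC"))
  mf <- data.frame(sample_id = colnames(tab), role = "query", source = "x",
                   stringsAsFactors = FALSE)
  rep <- screen_samples(tab, tx, mf, toy_db(), screening_config())
  sums <- rowSums(rep$per_sample[, c("potential_contaminant",
                                     "seawater_influenced", "endemic",
                                     "below_threshold", "unassigned")])
  expect_true(all(abs(sums - 1) < 1e-9))

  perm_f <- sample(nrow(tab)); perm_s <- sample(ncol(tab))
  rep2 <- screen_samples(tab[perm_f, perm_s], tx, mf[perm_s, ], toy_db(),
                         screening_config())
  m1 <- rep$per_sample[order(rep$per_sample$sample_id), ]
  m2 <- rep2$per_sample[order(rep2$per_sample$sample_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)

  # an order in both database sets is never labelled seawater_influenced
  both <- rep$detail[rep$detail$in_laboratory & rep$detail$in_seawater, ]
  expect_false(any(both$label == "seawater_influenced"))

  # with the threshold at zero nothing lands in below_threshold
  rep0 <- screen_samples(tab, tx, mf, toy_db(),
                         screening_config(per_sample_threshold = 0))
  expect_true(all(rep0$per_sample$below_threshold == 0))
})

test_that("database coverage equals a direct sum over member orders", {
  db <- toy_db()
  prof <- c(Burkholderiales = 0.6, Deepsealesales = 0.4)
  expect_equal(database_coverage(prof, db), 0.6)
  expect_equal(database_coverage(c(Burkholderiales = 1), db), 1.0)
  expect_equal(database_coverage(c(Deepsealesales = 1), db), 0.0)
  set.seed(9)
  orders <- unique(c(db$laboratory$order, db$seawater$order, paste0("End", 1:5)))
  p <- as.numeric(stats::rmultinom(1, 1000, rep(1, length(orders)))) / 1000
  names(p) <- orders
  members <- union(db$laboratory$order, db$seawater$order)
  expect_equal(database_coverage(p, db),
               sum(p[intersect(names(p), members)]))
})

test_that("zero-read query samples are skipped with a warning", {
  b <- screen_fixture()
  tab <- cbind(b$table, q3 = rep(0L, nrow(b$table)))
  mf <- rbind(b$manifest, data.frame(sample_id = "q3", role = "query",
                                     source = "sediment core"))
  expect_warning(
    rep <- screen_samples(tab, b$taxonomy, mf, toy_db(),
                          screening_config(min_reads = 0, min_occurrence = 0)),
    "zero-read")
  expect_identical(sort(rep$per_sample$sample_id), c("q1", "q2"))
})

test_that("rank mismatch between database and config is rejected", {
  b <- screen_fixture()
  db_class <- database_from_orders("Gammaproteobacteria", "Alphaproteobacteria",
                                   rank = "class")
  expect_error(screen_samples(b$table, b$taxonomy, b$manifest, db_class,
                              screening_config()), "rank")
})

test_that("contamination summaries count both tails against each cutoff", {
  per <- data.frame(sample_id = c("a", "b", "c"),
                    potential_contaminant = c(0.1, 0.3, 0.6),
                    seawater_influenced = 0, endemic = 0,
                    below_threshold = 0, unassigned = 0,
                    coverage = 1, total_reads = 100L, stringsAsFactors = FALSE)
  rep <- structure(list(per_sample = per), class = "screening_report")
  s <- summarize_contamination(rep, cutoffs = 0.2)
  expect_identical(s$n_above, 2L)
  expect_equal(s$frac_above, 2 / 3)
  expect_identical(s$n_at_or_below, 1L)

  empty <- structure(list(per_sample = per[0, ]), class = "screening_report")
  s0 <- summarize_contamination(empty, cutoffs = c(0.2, 0.5))
  expect_identical(s0$n_above, c(0L, 0L))

  # excluding seawater from the load changes the tallies accordingly
  per$seawater_influenced <- c(0.15, 0, 0)
  rep2 <- structure(list(per_sample = per), class = "screening_report")
  expect_identical(summarize_contamination(rep2, 0.2)$n_above, 3L)
  expect_identical(summarize_contamination(rep2, 0.2,
                                           include_seawater = FALSE)$n_above, 2L)

  # random reports match a brute-force recount
  set.seed(13)
  pr <- data.frame(sample_id = sprintf("s%02d", 1:25),
                   potential_contaminant = stats::runif(25, 0, 0.7),
                   seawater_influenced = stats::runif(25, 0, 0.3),
                   endemic = 0, below_threshold = 0, unassigned = 0,
                   coverage = 1, total_reads = 100L, stringsAsFactors = FALSE)
  repr <- structure(list(per_sample = pr), class = "screening_report")
  for (cut in c(0.2, 0.5, 0.9)) {
    brute <- sum(pr$potential_contaminant + pr$seawater_influenced > cut)
    expect_identical(summarize_contamination(repr, cut)$n_above, as.integer(brute))
  }
})

test_that("report writing emits the three output tables", {
  b <- screen_fixture()
  rep <- screen_samples(b$table, b$taxonomy, b$manifest, toy_db(),
                        screening_config(min_reads = 0, min_occurrence = 0))
  out <- tempfile()
  paths <- write_screening_report(rep, out)
  expect_true(all(file.exists(paths)))
  per <- utils::read.delim(paths[["per_sample"]])
  expect_identical(nrow(per), 2L)
  long <- utils::read.delim(paths[["detail"]])
  expect_true(all(c("sample_id", "order", "fraction", "label") %in% names(long)))
})
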
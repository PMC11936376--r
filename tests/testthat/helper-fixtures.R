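# Small in-code fixtures shared across test files.

tiny_table <- function() {
  m <- matrix(c(3L, 0L, 2L,
                1L, 7L, 0L,
                0L, 0L, 0L,
                5L, 5L, 5L),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("f1", "f2", "f3", "f4"),
                              c("s1", "s2", "s3")))
  feature_table(m)
}

tiny_taxonomy <- function() {
  data.frame(
    feature_id = c("f1", "f2", "f3", "f4"),
    domain = "Bacteria",
    phylum = c("Pseudomonadota", "Pseudomonadota", NA, "Bacillota"),
    class = c("Gammaproteobacteria", "Gammaproteobacteria", NA, "Bacilli"),
    order = c("Burkholderiales", "Burkholderiales", NA, "Bacillales"),
    family = c("Burkholderiaceae", NA, NA, "Bacillaceae"),
    genus = c("Ralstonia", NA, NA, NA),
    stringsAsFactors = FALSE)
}

tiny_manifest <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             role = c("control_I", "control_III", "query"),
             source = c("drilling fluid", "seawater", "sediment core"),
             stringsAsFactors = FALSE)
}

# Random count table with reproducible contents; allows zero rows/columns.
random_table <- function(n_features, n_samples, seed, lambda = 4) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_features * n_samples, lambda) *
                stats::rbinom(n_features * n_samples, 1, 0.7),
              nrow = n_features,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              sprintf("s%03d", seq_len(n_samples))))
  feature_table(m)
}

# Random taxonomy assigning each feature one of a few orders (or none).
random_taxonomy <- function(feature_ids, seed, orders = paste0("Order", LETTERS[1:6]),
                            p_missing = 0.15) {
  set.seed(seed)
  lab <- sample(orders, length(feature_ids), replace = TRUE)
  lab[stats::runif(length(lab)) < p_missing] <- NA
  data.frame(feature_id = feature_ids, domain = "Bacteria",
             phylum = NA_character_, class = NA_character_, order = lab,
             family = NA_character_, genus = NA_character_,
             stringsAsFactors = FALSE)
}

# A small two-pool database for labelling tests.
toy_db <- function() {
  database_from_orders(laboratory = c("Burkholderiales", "Bacillales"),
                       seawater = c("Burkholderiales", "Nitrosopumilales"))
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
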
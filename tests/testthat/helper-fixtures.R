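# Shared fixture builders; everything is generated in code.

make_features <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, feature_names()))
}

make_table <- function(n = 10, labels = NULL, seed = 1) {
  if (is.null(labels)) labels <- rep(c("W", "N3"), length.out = n)
  sample_table(make_features(n, seed), labels)
}

# A small graph dataset with two separable classes.
make_small_graph <- function(n = 12, seed = 1, train_fraction = 0.75) {
  set.seed(seed)
  half <- n %/% 2
  X <- rbind(matrix(rnorm(half * 6, mean = 2), half, 6),
             matrix(rnorm((n - half) * 6, mean = -2), n - half, 6))
  colnames(X) <- feature_names()
  tab <- sample_table(X, rep(c("W", "N3"), c(half, n - half)))
  edges <- pairwise_edge_table(tab, "spearman")
  assemble_graph(tab, edges, train_fraction, split_seed = seed)
}

# Per-class sub-tables realizing given counts, for merge tests.
subtables_for_counts <- function(counts, seed = 1) {
  lapply(seq_along(counts), function(i) {
    n <- counts[i]
    sample_table(make_features(n, seed + i), rep(names(counts)[i], n),
                 source_tag = paste0("sub", i))
  })
}

expect_tables_equal <- function(a, b, tolerance = 0) {
  expect_equal(nrow(a), nrow(b))
  expect_identical(a$label, b$label)
  expect_identical(a$sample_id, b$sample_id)
  for (col in feature_names()) {
    if (tolerance == 0) {
      expect_identical(a[[col]], b[[col]])
    } else {
      expect_equal(a[[col]], b[[col]], tolerance = tolerance)
    }
  }
}
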
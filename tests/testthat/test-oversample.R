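test_that("smote hits exact per-class targets and preserves originals", {
  tab <- anesthesia_cohort(seed = 4)
  spec <- oversample_spec(smote_targets(), seed = 7)
  aug <- smote(tab, spec)
  expect_equal(nrow(aug), 1197)
  cc <- class_counts(aug)
  expect_equal(unname(cc[names(smote_targets())]),
               unname(smote_targets()))
  # originals verbatim and first
  expect_equal(as.matrix(as.data.frame(aug)[1:290, feature_names()]),
               as.matrix(as.data.frame(tab)[feature_names()]),
               ignore_attr = TRUE)
  expect_true(all(aug$source_tag[-(1:290)] == "synthetic_smote"))
})

test_that("smote synthetic points are convex combinations within class", {
  set.seed(3)
  tab <- make_table(30, labels = rep(c("W", "REM", "BI"), each = 10))
  targets <- c(W = 18L, REM = 16L, BI = 15L)
  aug <- smote(tab, oversample_spec(targets, k_neighbors = 3, seed = 1))
  X0 <- as.matrix(as.data.frame(tab)[feature_names()])
  Xs <- as.matrix(as.data.frame(aug)[feature_names()])
  synth <- which(aug$source_tag == "synthetic_smote")
  for (i in synth) {
    cls <- which(tab$label == aug$label[i])
    found <- FALSE
    for (a in cls) {
      for (b in setdiff(cls, a)) {
        seg <- Xs[i, ] - X0[a, ]
        dir <- X0[b, ] - X0[a, ]
        nz <- which(abs(dir) > 1e-12)
        u <- seg[nz] / dir[nz]
        zero_ok <- length(nz) == 6 || all(abs(seg[-nz]) < 1e-9)
        if (zero_ok && diff(range(u)) < 1e-8 &&
            u[1] >= -1e-12 && u[1] <= 1 + 1e-12) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    expect_true(found, label = paste("synthetic row", i,
                                     "lies on a within-class segment"))
  }
})

test_that("two-point class interpolation stays on the segment", {
  X <- make_features(2, seed = 5)
  tab <- sample_table(X, c("REM", "REM"))
  aug <- smote(tab, oversample_spec(c(REM = 3L), k_neighbors = 1, seed = 2))
  s <- as.numeric(as.data.frame(aug)[3, feature_names()])
  d <- X[2, ] - X[1, ]
  u <- (s - X[1, ]) / d
  expect_equal(max(u) - min(u), 0, tolerance = 1e-10)
  expect_gte(u[1], 0)
  expect_lte(u[1], 1)
})

test_that("oversampling is deterministic, label-pure and validates targets", {
  tab <- anesthesia_cohort(seed = 4)
  spec <- oversample_spec(smote_targets(), seed = 7)
  expect_tables_equal(smote(tab, spec), smote(tab, spec))

  aug <- smote(tab, spec)
  expect_identical(sort(unique(aug$label)), sort(unique(tab$label)))

  # no-op when targets equal current counts
  cc <- class_counts(tab)
  same <- smote(tab, oversample_spec(cc[cc > 0], seed = 1))
  expect_equal(nrow(same), nrow(tab))
  expect_equal(as.matrix(as.data.frame(same)[feature_names()]),
               as.matrix(as.data.frame(tab)[feature_names()]),
               ignore_attr = TRUE)

  expect_error(smote(tab, oversample_spec(c(W = 5L), seed = 1)),
               "below its current count")
  expect_error(smote(tab, oversample_spec(c(EO = 10L), seed = 1)),
               "no records present")
})

test_that("singleton classes are duplicated rather than interpolated", {
  tab <- make_table(3, c("W", "W", "HC"))
  aug <- smote(tab, oversample_spec(c(HC = 4L), seed = 1))
  X <- as.matrix(as.data.frame(aug)[feature_names()])
  hc <- which(aug$label == "HC")
  expect_length(hc, 4)
  for (i in hc[-1]) expect_equal(X[i, ], X[hc[1], ])
})

test_that("random oversampling duplicates in-class originals exactly", {
  tab <- anesthesia_cohort(seed = 4)
  aug <- random_oversample(tab, smote_targets(), seed = 9)
  expect_equal(nrow(aug), 1197)
  cc <- class_counts(aug)
  expect_equal(unname(cc[names(smote_targets())]),
               unname(smote_targets()))
  X0 <- as.data.frame(tab)[feature_names()]
  Xs <- as.data.frame(aug)[feature_names()]
  synth <- which(aug$source_tag == "synthetic_duplicate")
  key0 <- do.call(paste, c(X0, list(tab$label)))
  keys <- do.call(paste, c(Xs[synth, ], list(aug$label[synth])))
  expect_true(all(keys %in% key0))

  expect_tables_equal(random_oversample(tab, smote_targets(), seed = 9),
                      aug)
})
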
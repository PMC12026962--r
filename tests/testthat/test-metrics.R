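test_that("confusion_matrix tallies true rows against predicted columns", {
  cm <- confusion_matrix(c("W", "W", "N3", "N3", "N3"),
                         c("W", "N3", "N3", "N3", "W"),
                         label_order = c("W", "N3"))
  expect_equal(unclass(cm), matrix(c(1L, 1L, 1L, 2L), 2, 2,
                                   dimnames = list(true = c("W", "N3"),
                                                   pred = c("W", "N3"))),
               ignore_attr = FALSE)

  perfect <- confusion_matrix(rep(state_labels(), 3),
                              rep(state_labels(), 3))
  expect_true(all(perfect[upper.tri(perfect)] == 0))
  expect_true(all(perfect[lower.tri(perfect)] == 0))
  expect_equal(sum(diag(perfect)), 30)

  empty <- confusion_matrix(character(0), character(0))
  expect_equal(sum(empty), 0)

  expect_error(confusion_matrix("W", "QQ"), "QQ")
  expect_error(metric_panel(empty), "empty")
})

test_that("metric_panel reproduces hand arithmetic on a binary matrix", {
  cm <- confusion_matrix(rep(c("W", "N3"), c(60, 40)),
                         c(rep("W", 50), rep("N3", 10),
                           rep("W", 5), rep("N3", 35)),
                         label_order = c("W", "N3"))
  expect_equal(unclass(cm)[1, ], c(W = 50L, N3 = 10L))
  rep1 <- metric_panel(cm)
  expect_equal(rep1$accuracy, 0.85)
  pc <- rep1$per_class
  expect_equal(pc$sensitivity[pc$label == "W"], 50 / 60)
  expect_equal(pc$precision[pc$label == "W"], 50 / 55)
  expect_equal(pc$fdr[pc$label == "W"], 1 - 50 / 55)
  expect_equal(pc$fnr[pc$label == "W"], 1 - 50 / 60)
  # macro averages over the two one-vs-rest panels
  expect_equal(rep1$sensitivity, mean(c(50 / 60, 35 / 40)))
  expect_equal(rep1$precision, mean(c(50 / 55, 35 / 45)))
})

test_that("perfect predictions score 1 across the panel", {
  y <- rep(c("W", "DS", "N3", "UWS"), 5)
  rep0 <- metric_panel(confusion_matrix(y, y,
                                        c("W", "DS", "N3", "UWS")))
  expect_equal(rep0$accuracy, 1)
  expect_equal(rep0$sensitivity, 1)
  expect_equal(rep0$specificity, 1)
  expect_equal(rep0$fpr, 0)
  expect_equal(rep0$fdr, 0)
  expect_equal(rep0$fnr, 0)
  expect_equal(rep0$mcc, 1)
  expect_equal(rep0$kappa, 1)
})

test_that("metric_panel matches direct TP/FP/FN/TN formulas on random 2x2", {
  set.seed(99)
  for (i in 1:500) {
    m <- matrix(rpois(4, 20), 2, 2,
                dimnames = list(true = c("W", "N3"),
                                pred = c("W", "N3")))
    if (sum(m) == 0 || any(rowSums(m) == 0)) next
    cm <- structure(m, class = c("confusion_matrix", "matrix", "array"))
    rep1 <- suppressWarnings(metric_panel(cm))
    tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
    sens <- c(tp / (tp + fn), tn / (tn + fp))
    prec <- c(tp / (tp + fp), tn / (tn + fn))
    sens[is.nan(sens)] <- 0
    prec[is.nan(prec)] <- 0
    expect_equal(rep1$accuracy, (tp + tn) / sum(m))
    expect_equal(rep1$sensitivity, mean(sens))
    expect_equal(rep1$precision, mean(prec))
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    if (den > 0) {
      expect_equal(rep1$mcc, (tp * tn - fp * fn) / den, tolerance = 1e-12)
    }
  }
})

test_that("cohen_kappa matches hand arithmetic and edge cases", {
  mk <- function(m) {
    structure(m, class = c("confusion_matrix", "matrix", "array"))
  }
  expect_equal(cohen_kappa(mk(diag(c(5L, 7L, 3L)))), 1)
  expect_equal(cohen_kappa(mk(matrix(25L, 2, 2))), 0)
  # p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  expect_equal(cohen_kappa(mk(matrix(c(20L, 10L, 5L, 15L), 2, 2))), 0.4)
})

test_that("a constant predictor is chance level under MCC and kappa", {
  y <- rep(c("W", "N3"), c(30, 70))
  pred <- rep("N3", 100)
  cm <- confusion_matrix(y, pred, c("W", "N3"))
  rep1 <- suppressWarnings(metric_panel(cm))
  expect_equal(rep1$mcc, 0)
  expect_equal(rep1$kappa, 0)
})

test_that("macro metrics are invariant to label order and count scaling", {
  set.seed(17)
  y <- sample(c("W", "DS", "N3"), 200, replace = TRUE)
  p <- ifelse(runif(200) < 0.7, y,
              sample(c("W", "DS", "N3"), 200, replace = TRUE))
  o1 <- c("W", "DS", "N3")
  o2 <- c("N3", "W", "DS")
  r1 <- metric_panel(confusion_matrix(y, p, o1))
  r2 <- metric_panel(confusion_matrix(y, p, o2))
  for (k in c("accuracy", "sensitivity", "precision", "specificity",
              "npv", "fpr", "fdr", "fnr", "f1", "mcc", "kappa")) {
    expect_equal(r1[[k]], r2[[k]], label = k)
  }

  cm <- confusion_matrix(y, p, o1)
  cm3 <- structure(unclass(cm) * 3L,
                   class = c("confusion_matrix", "matrix", "array"))
  r3 <- metric_panel(cm3)
  expect_equal(r1$mcc, r3$mcc)
  expect_equal(r1$kappa, r3$kappa)
})

test_that("panel values stay inside their ranges on random matrices", {
  set.seed(31)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 5), k, k,
                dimnames = list(true = state_labels()[1:k],
                                pred = state_labels()[1:k]))
    if (any(rowSums(m) == 0) || sum(m) == 0) next
    r <- suppressWarnings(metric_panel(
      structure(m, class = c("confusion_matrix", "matrix", "array"))))
    rates <- c(r$accuracy, r$sensitivity, r$precision, r$specificity,
               r$npv, r$fpr, r$fdr, r$fnr, r$f1)
    expect_true(all(rates >= 0 & rates <= 1))
    expect_gte(r$mcc, -1)
    expect_lte(r$mcc, 1)
    expect_gte(r$kappa, -1)
    expect_lte(r$kappa, 1)
  }
})

test_that("reports serialize to yaml and csv grids", {
  y <- rep(c("W", "N3"), c(10, 10))
  p <- c(rep("W", 9), "N3", rep("N3", 8), "W", "W")
  rep1 <- metric_panel(confusion_matrix(y, p, c("W", "N3")))
  dir <- withr::local_tempdir()
  write_metrics_report(rep1, dir)
  got <- yaml::read_yaml(file.path(dir, "metrics.yaml"))
  expect_equal(got$accuracy, rep1$accuracy, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "per_class_metrics.csv")))
  expect_true(file.exists(file.path(dir, "confusion_matrix.csv")))
})
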
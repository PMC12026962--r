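# Confusion matrix and the multiclass evaluation panel. All rate metrics
# are macro-averaged one-vs-rest values (per-class rates averaged with
# equal class weight), the convention most consistent with evaluating a
# deliberately imbalanced cohort; micro-averaging would give different
# numbers. MCC uses the generalized matrix-correlation form, which
# reduces to the familiar binary formula for two classes.

#' Confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors (character or factor);
#'   every value must appear in `label_order`.
#' @param label_order ordered labels indexing rows (true class) and
#'   columns (predicted class).
#' @return a `confusion_matrix`: K x K integer matrix of counts.
#' @export
confusion_matrix <- function(y_true, y_pred,
                             label_order = state_labels()) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  unknown <- setdiff(unique(c(y_true, y_pred)), label_order)
  if (length(unknown) > 0) {
    stop("label(s) outside label_order: ", paste(unknown, collapse = ", "))
  }
  cm <- table(factor(y_true, levels = label_order),
              factor(y_pred, levels = label_order))
  cm <- matrix(as.integer(cm), nrow = length(label_order),
               dimnames = list(true = label_order, pred = label_order))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

safe_ratio <- function(num, den, what) {
  out <- num / den
  bad <- den == 0
  if (any(bad)) {
    warning("undefined ", what, " (0/0) for ", sum(bad),
            " class(es); contributing 0")
    out[bad] <- 0
  }
  out
}

#' Multiclass evaluation panel
#'
#' Computes per-class one-vs-rest TP/FP/FN/TN and the derived rates
#' (sensitivity, precision, specificity, NPV, FPR, FDR, FNR, F1), then
#' macro-averages them over the classes present in the true labels.
#' Accuracy is `trace / total`; MCC is the generalized multiclass
#' correlation over the full matrix; kappa is Cohen's chance-corrected
#' agreement. Per-class 0/0 ratios contribute 0 with a warning.
#'
#' @param cm a [confusion_matrix] with a positive total.
#' @return a `metrics_report` list: the scalar panel (`accuracy`,
#'   `sensitivity`, `precision`, `specificity`, `npv`, `fpr`, `fdr`,
#'   `fnr`, `f1`, `mcc`, `kappa`) plus `per_class` (data frame) and the
#'   matrix itself.
#' @export
metric_panel <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  row_tot <- rowSums(cm)
  col_tot <- colSums(cm)
  present <- which(row_tot > 0)

  tp <- diag(cm)[present]
  fn <- row_tot[present] - tp
  fp <- col_tot[present] - tp
  tn <- total - tp - fn - fp

  sens <- safe_ratio(tp, tp + fn, "sensitivity")
  prec <- safe_ratio(tp, tp + fp, "precision")
  spec <- safe_ratio(tn, tn + fp, "specificity")
  npv <- safe_ratio(tn, tn + fn, "NPV")
  f1 <- safe_ratio(2 * tp, 2 * tp + fp + fn, "F1")

  per_class <- data.frame(
    label = rownames(cm)[present],
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, precision = prec, specificity = spec,
    npv = npv, fpr = 1 - spec, fdr = 1 - prec, fnr = 1 - sens, f1 = f1,
    row.names = NULL)

  report <- list(
    accuracy = sum(diag(cm)) / total,
    sensitivity = mean(sens),
    precision = mean(prec),
    specificity = mean(spec),
    npv = mean(npv),
    fpr = mean(1 - spec),
    fdr = mean(1 - prec),
    fnr = mean(1 - sens),
    f1 = mean(f1),
    mcc = multiclass_mcc(cm),
    kappa = cohen_kappa(cm),
    per_class = per_class,
    confusion = cm)
  structure(report, class = "metrics_report")
}

# Generalized MCC: covariance between the true and predicted indicator
# matrices, normalized by their standard deviations. Zero denominator
# (a constant truth or constant prediction) yields 0 with a warning.
multiclass_mcc <- function(cm) {
  s <- sum(cm)
  c_tr <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c_tr * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) {
    warning("undefined MCC (degenerate marginals); returning 0")
    return(0)
  }
  num / den
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/total` and expected agreement
#' `p_e = sum(row_i * col_i) / total^2`.
#'
#' @param cm a [confusion_matrix] with a positive total.
#' @return kappa in `[-1, 1]`; errors when `p_e == 1` (degenerate
#'   single-cell concentration).
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe == 1) {
    if (po == 1) return(1)
    stop("undefined kappa: expected agreement equals 1")
  }
  (po - pe) / (1 - pe)
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Multiclass evaluation panel (macro one-vs-rest averages)\n")
  keys <- c("accuracy", "sensitivity", "precision", "specificity", "npv",
            "fpr", "fdr", "fnr", "f1", "mcc", "kappa")
  vals <- vapply(keys, function(k) x[[k]], numeric(1))
  print(round(vals, digits))
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes the scalar panel as a key-value YAML document, the per-class
#' breakdown and confusion matrix as comma-separated grids.
#'
#' @param report a `metrics_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- c("accuracy", "sensitivity", "precision", "specificity", "npv",
            "fpr", "fdr", "fnr", "f1", "mcc", "kappa")
  scalars <- lapply(keys, function(k) report[[k]])
  names(scalars) <- keys
  yaml::write_yaml(scalars, file.path(dir, "metrics.yaml"))
  write.csv(report$per_class, file.path(dir, "per_class_metrics.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(unclass(report$confusion)),
            file.path(dir, "confusion_matrix.csv"))
  invisible(dir)
}
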
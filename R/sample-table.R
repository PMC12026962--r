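#' @useDynLib anesgraph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor dist rnorm runif sd setNames
#' @importFrom utils read.table write.table write.csv read.csv head
NULL

#' Brain-state labels and feature columns
#'
#' The closed set of brain-state labels handled by the package: wakefulness
#' (W), drowsy sleep (DS), eyes open / eyes closed (EO, EC), NREM sleep
#' stages 3 and 2 (N3, N2), unresponsive wakefulness syndrome (UWS), REM
#' sleep (REM), brain injury (BI) and healthy control (HC). Unknown label
#' strings are rejected at parse time.
#'
#' @format `state_labels()` returns a character vector of the 10 labels;
#'   `feature_names()` returns the canonical feature order: activations of
#'   the ventral posterior lateral (VPL), pulvinar (PUL) and mediodorsal
#'   (MD) thalamic nuclei, white matter (WM), cerebrospinal fluid (CSF) and
#'   right VPL (rVPL).
#' @export
state_labels <- function() {
  c("W", "DS", "EO", "EC", "N3", "UWS", "REM", "N2", "BI", "HC")
}

#' @rdname state_labels
#' @export
feature_names <- function() {
  c("VPL", "PUL", "MD", "WM", "CSF", "rVPL")
}

#' Construct a sample table
#'
#' A sample table is the tabular substrate of the whole pipeline: one row
#' per sample with a positive integer id, six finite real activation
#' features in canonical order, a brain-state label from the closed label
#' set, and a free-form source tag naming the contributing sub-dataset.
#'
#' @param features numeric matrix or data frame with the six feature
#'   columns (any order; matched by name).
#' @param label character or factor vector of brain-state labels.
#' @param sample_id integer ids, defaults to `1:n`.
#' @param source_tag character vector (recycled) naming the origin of each
#'   record.
#' @return an object of class `sample_table` (a data frame).
#' @export
sample_table <- function(features, label, sample_id = NULL,
                         source_tag = "unknown") {
  features <- as.data.frame(features)
  missing_cols <- setdiff(feature_names(), names(features))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  features <- features[feature_names()]
  n <- nrow(features)
  if (is.null(sample_id)) sample_id <- seq_len(n)
  df <- data.frame(sample_id = as.integer(sample_id), features,
                   label = as.character(label),
                   source_tag = rep_len(as.character(source_tag), n),
                   stringsAsFactors = FALSE)
  validate_sample_table(df)
}

validate_sample_table <- function(df) {
  for (col in feature_names()) {
    v <- df[[col]]
    if (!is.numeric(v)) stop("feature column '", col, "' is not numeric")
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop("non-finite value in feature '", col, "' at row ", bad[1])
    }
  }
  unknown <- setdiff(unique(df$label), state_labels())
  if (length(unknown) > 0) {
    stop("unknown state label(s): ", paste(unknown, collapse = ", "))
  }
  if (any(df$sample_id < 1L) || anyNA(df$sample_id)) {
    stop("sample_id must be a positive integer")
  }
  if (anyDuplicated(df$sample_id)) stop("sample_id values must be unique")
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from a delimited file
#'
#' Expects a header row naming `sample_id`, the six feature columns and
#' `label` (plus an optional `source_tag`); column order on disk is
#' irrelevant, the table is normalized to the canonical feature order.
#'
#' @param path file to read.
#' @param delimiter field separator, comma by default.
#' @return a [sample_table].
#' @export
read_sample_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = delimiter,
                   stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", feature_names(), "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$source_tag)) df$source_tag <- "unknown"
  df <- df[c("sample_id", feature_names(), "label", "source_tag")]
  df$sample_id <- as.integer(df$sample_id)
  validate_sample_table(df)
}

#' Write a sample table to a delimited file
#'
#' Feature values are written with 17 significant digits so that
#' [read_sample_table()] inverts the write exactly at double precision.
#'
#' @param table a [sample_table].
#' @param path destination file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "sample_table"))
  out <- table
  for (col in feature_names()) out[[col]] <- sprintf("%.17g", out[[col]])
  ok <- tryCatch({
    write.table(out, path, sep = delimiter, row.names = FALSE,
                quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write sample table to '", path, "': ",
         conditionMessage(e))
  })
  invisible(path)
}

#' Merge sample tables
#'
#' Plain concatenation in input order, mirroring the union of per-study
#' feature tables: no deduplication, source tags preserved, sample ids
#' reassigned contiguously 1..N.
#'
#' @param tables list of [sample_table] objects.
#' @return the merged [sample_table].
#' @export
merge_tables <- function(tables) {
  if (!is.list(tables) || length(tables) == 0 ||
      inherits(tables, "sample_table")) {
    stop("merge_tables() expects a non-empty list of sample tables")
  }
  for (t in tables) stopifnot(inherits(t, "sample_table"))
  merged <- do.call(rbind, lapply(tables, as.data.frame))
  merged$sample_id <- seq_len(nrow(merged))
  validate_sample_table(merged)
}

#' Class counts of a sample table
#'
#' @param table a [sample_table].
#' @return named integer vector over all 10 labels; absent labels map to 0.
#' @export
class_counts <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  counts <- base::table(factor(table$label, levels = state_labels()))
  stats::setNames(as.integer(counts), names(counts))
}

#' @export
print.sample_table <- function(x, ...) {
  cat("Sample table:", nrow(x), "records\n")
  cc <- class_counts(x)
  cc <- cc[cc > 0]
  if (length(cc) > 0) {
    cat("Class counts:",
        paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}
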
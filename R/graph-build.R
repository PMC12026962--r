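# Sample-similarity graph construction. Every sample becomes a node; every
# unordered pair of samples gets one undirected edge weighted by a
# similarity between their 6-feature rows. Spearman rank correlation is the
# primary weighting (it keys on the rank profile of the six activations
# within a row); cosine similarity and a bounded Euclidean transform are
# the comparison methods.

#' Spearman rank correlation of two feature vectors
#'
#' Defined as the Pearson correlation of within-vector midranks, which
#' equals the classical closed form `1 - 6*sum(d^2) / (p*(p^2-1))` (d the
#' rank differences, p the vector length) whenever both vectors are free
#' of ties.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return the correlation, in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("undefined Spearman correlation: constant vector")
  }
  cor(rx, ry)
}

#' Cosine similarity of two feature vectors
#'
#' @param x,y nonzero numeric vectors of equal length.
#' @return the cosine of the angle between them, in `[-1, 1]`.
#' @export
cosine_sim <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("undefined cosine similarity: zero vector")
  sum(x * y) / (nx * ny)
}

#' Euclidean-derived edge weight
#'
#' Maps the Euclidean distance d between two feature vectors to the
#' bounded similarity `1 / (1 + d)`, so all three edge-weight methods
#' produce comparable magnitudes: the weight lies in `(0, 1]` and equals 1
#' exactly when `x == y`.
#'
#' @param x,y finite numeric vectors of equal length.
#' @return the weight, in `(0, 1]`.
#' @export
euclidean_weight <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  1 / (1 + sqrt(sum((x - y)^2)))
}

#' Build the full pairwise edge list of a sample table
#'
#' One edge per unordered sample pair `{i, j}` with `i < j` (canonical
#' orientation), `n*(n-1)/2` edges in total, weighted by the chosen
#' method. For the Spearman method a sample with six identical feature
#' values has no defined rank correlation; the default policy is to raise
#' an error naming the sample, `on_constant = "zero"` instead assigns
#' weight 0 to its edges.
#'
#' @param table a [sample_table] with at least 2 records (1 gives an empty
#'   edge list).
#' @param method `"spearman"`, `"cosine"` or `"euclidean"`.
#' @param on_constant policy for rank-degenerate samples under the
#'   Spearman method: `"error"` (default) or `"zero"`.
#' @return an `edge_list`: a data frame with integer columns `target` <
#'   `source` and numeric `weight`, plus a `method` attribute.
#' @export
pairwise_edge_table <- function(table,
                                method = c("spearman", "cosine",
                                           "euclidean"),
                                on_constant = c("error", "zero")) {
  stopifnot(inherits(table, "sample_table"))
  method <- match.arg(method)
  on_constant <- match.arg(on_constant)
  X <- as.matrix(as.data.frame(table)[feature_names()])
  n <- nrow(X)
  if (n < 2) {
    return(edge_list(integer(0), integer(0), numeric(0), method))
  }
  W <- switch(method,
    spearman = {
      R <- t(apply(X, 1, rank, ties.method = "average"))
      degen <- which(apply(R, 1, sd) == 0)
      if (length(degen) > 0 && on_constant == "error") {
        stop("undefined Spearman weight: sample ", degen[1],
             " has constant features (use on_constant = \"zero\")")
      }
      Wm <- suppressWarnings(cor(t(R)))
      if (length(degen) > 0) {
        Wm[degen, ] <- 0
        Wm[, degen] <- 0
      }
      Wm
    },
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      zero <- which(nrm == 0)
      if (length(zero) > 0) {
        stop("undefined cosine weight: sample ", zero[1],
             " is the zero vector")
      }
      tcrossprod(X / nrm)
    },
    euclidean = 1 / (1 + as.matrix(dist(X))))
  tg <- rep.int(seq_len(n - 1), (n - 1):1)
  sr <- sequence((n - 1):1) + tg
  edge_list(tg, sr, W[cbind(tg, sr)], method)
}

edge_list <- function(target, source, weight, method) {
  df <- data.frame(target = as.integer(target),
                   source = as.integer(source),
                   weight = as.numeric(weight))
  if (any(df$target >= df$source)) {
    stop("edges must satisfy target < source (no self-loops)")
  }
  if (anyDuplicated(df[c("target", "source")])) {
    stop("duplicate edges are not allowed")
  }
  attr(df, "method") <- method
  class(df) <- c("edge_list", "data.frame")
  df
}

#' Filter an edge list by a weight threshold
#'
#' Retains exactly the edges whose weight is less than or equal to `tau`
#' (inclusive). With correlation-bounded weights, `tau = 1` keeps every
#' edge; the filter is idempotent and monotone in `tau`.
#'
#' @param edges an `edge_list`.
#' @param tau threshold.
#' @return the filtered `edge_list`.
#' @export
threshold_filter <- function(edges, tau) {
  stopifnot(inherits(edges, "edge_list"), is.numeric(tau),
            length(tau) == 1)
  out <- edges[edges$weight <= tau, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- attr(edges, "method")
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Edge-table file I/O
#'
#' The on-disk layout is a comma-separated file with header
#' `Target,Source,Correlation`, 1-based node ids and weights printed at 6
#' decimal places; `read_edge_table()` inverts `write_edge_table()` at
#' that precision.
#'
#' @param edges an `edge_list`.
#' @param path file path.
#' @return `write_edge_table()`: `path` invisibly; `read_edge_table()`:
#'   an `edge_list`.
#' @export
write_edge_table <- function(edges, path) {
  stopifnot(inherits(edges, "edge_list"))
  lines <- c("Target,Source,Correlation",
             sprintf("%d,%d,%.6f", edges$target, edges$source,
                     edges$weight))
  ok <- tryCatch(writeLines(lines, path), error = function(e) {
    stop("cannot write edge table to '", path, "': ",
         conditionMessage(e))
  })
  invisible(path)
}

#' @rdname write_edge_table
#' @param method method tag to attach to the edge list read from disk.
#' @export
read_edge_table <- function(path, method = "spearman") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 ||
      gsub("\\s", "", lines[1]) != "Target,Source,Correlation") {
    stop("malformed edge table header in '", path, "'")
  }
  if (length(lines) == 1) {
    return(edge_list(integer(0), integer(0), numeric(0), method))
  }
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    stop("malformed edge table row at line ", bad[1] + 1)
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  tg <- suppressWarnings(as.integer(m[, 1]))
  sr <- suppressWarnings(as.integer(m[, 2]))
  w <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(tg) | is.na(sr) | is.na(w))
  if (length(bad) > 0) {
    stop("unparseable edge table row at line ", bad[1] + 1)
  }
  edge_list(tg, sr, w, method)
}

#' Assemble a transductive graph dataset
#'
#' Combines a sample table and its edge list into the classification
#' instance: a standardized node-feature matrix, node labels, the edge
#' list, and disjoint train/test masks from a stratified-by-label random
#' split. Features are z-scored with training-node statistics (the test
#' nodes' features are scaled with the same constants). Every class with
#' at least 2 members contributes at least one test and one train node;
#' singleton classes go to training with a warning.
#'
#' @param table a [sample_table].
#' @param edges an `edge_list` whose endpoints lie in `1..nrow(table)`.
#' @param train_fraction fraction of nodes used for training, in (0, 1).
#' @param split_seed integer seed for the stratified split.
#' @return a `graph_dataset` list with elements `features` (n x 6,
#'   standardized), `labels` (factor over the classes present), `edges`,
#'   `train_mask`, `test_mask`, `center`, `scale`.
#' @export
assemble_graph <- function(table, edges, train_fraction = 0.8,
                           split_seed = 1L) {
  stopifnot(inherits(table, "sample_table"), inherits(edges, "edge_list"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(table)
  if (nrow(edges) > 0 && (max(edges$source) > n || min(edges$target) < 1)) {
    stop("edge endpoints outside 1..", n)
  }
  present <- intersect(state_labels(), unique(table$label))
  labels <- factor(table$label, levels = present)

  set.seed(derive_seed(split_seed, 9000L))
  train_mask <- rep(FALSE, n)
  for (lab in present) {
    idx <- which(labels == lab)
    m <- length(idx)
    if (m == 1) {
      warning("class '", lab, "' has a single record; assigned to train")
      train_mask[idx] <- TRUE
      next
    }
    n_test <- round((1 - train_fraction) * m)
    n_test <- max(1L, min(m - 1L, n_test))
    test_idx <- sample(idx, n_test)
    train_mask[idx] <- TRUE
    train_mask[test_idx] <- FALSE
  }
  test_mask <- !train_mask

  X <- as.matrix(as.data.frame(table)[feature_names()])
  center <- colMeans(X[train_mask, , drop = FALSE])
  scale <- apply(X[train_mask, , drop = FALSE], 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  X <- sweep(sweep(X, 2, center), 2, scale, "/")

  structure(list(features = X, labels = labels, edges = edges,
                 train_mask = train_mask, test_mask = test_mask,
                 center = center, scale = scale),
            class = "graph_dataset")
}

# Directed edge arrays (both orientations, 0-based) consumed by the
# aggregation kernel; computed once per graph and cached on the dataset.
directed_edges <- function(graph) {
  cached <- attr(graph, "directed")
  if (!is.null(cached)) return(cached)
  e <- graph$edges
  out <- list(from = c(e$target, e$source) - 1L,
              to = c(e$source, e$target) - 1L,
              w = rep(e$weight, 2))
  out
}

# Precompute and attach the directed edge arrays (used once per training
# run so repeated forward passes do not rebuild them).
cache_directed <- function(graph) {
  attr(graph, "directed") <- directed_edges(graph)
  graph
}

#' @export
print.graph_dataset <- function(x, ...) {
  cat("Graph dataset:", nrow(x$features), "nodes,", nrow(x$edges),
      "undirected edges (", attr(x$edges, "method"), "weights )\n")
  cat("Classes:", paste(levels(x$labels), collapse = ", "), "\n")
  cat("Train/test:", sum(x$train_mask), "/", sum(x$test_mask), "\n")
  invisible(x)
}
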
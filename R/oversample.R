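# Minority-class oversampling with explicit per-class target counts. The
# targets are configuration, not a balance-to-majority rule: the study
# cohort's post-augmentation counts are deliberately unbalanced.

#' Specify an oversampling run
#'
#' @param targets named integer vector mapping brain-state labels to the
#'   desired post-augmentation count per class; every target must be at
#'   least the class's current count.
#' @param k_neighbors number of within-class nearest neighbors SMOTE
#'   interpolates toward (default 5, the value of the original SMOTE
#'   formulation); automatically reduced to `m - 1` for classes with `m`
#'   originals.
#' @param seed integer seed.
#' @return an `oversample_spec` object.
#' @export
oversample_spec <- function(targets, k_neighbors = 5L, seed = 1L) {
  stopifnot(is.numeric(targets), length(targets) >= 1,
            !is.null(names(targets)), k_neighbors >= 1)
  unknown <- setdiff(names(targets), state_labels())
  if (length(unknown) > 0) {
    stop("unknown label(s) in targets: ", paste(unknown, collapse = ", "))
  }
  if (any(targets < 1)) stop("targets must be positive")
  structure(list(targets = stats::setNames(as.integer(targets),
                                           names(targets)),
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "oversample_spec")
}

check_targets <- function(table, targets) {
  counts <- class_counts(table)
  for (lab in names(targets)) {
    if (counts[lab] == 0) {
      stop("cannot oversample class '", lab, "': no records present")
    }
    if (targets[lab] < counts[lab]) {
      stop("target for class '", lab, "' (", targets[lab],
           ") is below its current count (", counts[lab], ")")
    }
  }
  counts
}

# Rows of synthetic feature vectors for one class: each is
# x + u * (x_nn - x) with u ~ U[0,1], x a uniformly chosen original and
# x_nn one of its k nearest within-class neighbors under Euclidean
# distance (ties by index). A singleton class falls back to duplication,
# since interpolation is undefined with no neighbor.
smote_class <- function(X, n_new, k) {
  m <- nrow(X)
  if (m == 1) {
    return(X[rep(1, n_new), , drop = FALSE])
  }
  k <- min(k, m - 1)
  d <- as.matrix(dist(X))
  diag(d) <- Inf
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
  nn <- if (k == 1) matrix(nn, ncol = 1) else t(nn)
  donor <- sample.int(m, n_new, replace = TRUE)
  pick <- sample.int(k, n_new, replace = TRUE)
  u <- runif(n_new)
  neigh <- nn[cbind(donor, pick)]
  X[donor, , drop = FALSE] +
    u * (X[neigh, , drop = FALSE] - X[donor, , drop = FALSE])
}

oversample_core <- function(table, targets, seed, synth_fun, tag) {
  counts <- check_targets(table, targets)
  X_all <- as.matrix(as.data.frame(table)[feature_names()])
  parts <- list(as.data.frame(table))
  labs <- intersect(state_labels(), names(targets))  # canonical order
  for (lab in labs) {
    n_new <- targets[lab] - counts[lab]
    if (n_new == 0) next
    idx <- which(table$label == lab)
    set.seed(derive_seed(seed, 500L + match(lab, state_labels())))
    synth <- synth_fun(X_all[idx, , drop = FALSE], n_new)
    part <- data.frame(sample_id = NA_integer_, synth, label = lab,
                       source_tag = tag, stringsAsFactors = FALSE)
    colnames(part) <- c("sample_id", feature_names(), "label", "source_tag")
    parts[[length(parts) + 1]] <- part
  }
  out <- do.call(rbind, parts)
  out$sample_id <- seq_len(nrow(out))
  validate_sample_table(out)
}

#' SMOTE oversampling
#'
#' Synthetic Minority Over-sampling Technique: augments each targeted
#' class to an exact target count by interpolating between an original
#' record and one of its k within-class nearest neighbors. All original
#' records are preserved verbatim and come first; synthetic records carry
#' their donor's label and the source tag `"synthetic_smote"`.
#'
#' @param table a [sample_table].
#' @param spec an [oversample_spec].
#' @return the augmented [sample_table].
#' @export
smote <- function(table, spec) {
  stopifnot(inherits(table, "sample_table"),
            inherits(spec, "oversample_spec"))
  oversample_core(table, spec$targets, spec$seed,
                  function(X, n_new) smote_class(X, n_new,
                                                 spec$k_neighbors),
                  "synthetic_smote")
}

#' Random duplication oversampling
#'
#' Augments each targeted class by duplicating uniformly chosen in-class
#' originals (exact copies, source tag `"synthetic_duplicate"`).
#'
#' @param table a [sample_table].
#' @param targets named integer vector of per-class target counts.
#' @param seed integer seed.
#' @return the augmented [sample_table].
#' @export
random_oversample <- function(table, targets, seed = 1L) {
  stopifnot(inherits(table, "sample_table"))
  spec <- oversample_spec(targets, seed = seed)
  oversample_core(table, spec$targets, spec$seed,
                  function(X, n_new) {
                    X[sample.int(nrow(X), n_new, replace = TRUE), ,
                      drop = FALSE]
                  },
                  "synthetic_duplicate")
}
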
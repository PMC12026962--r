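# Seeded synthetic cohorts with class-conditional Gaussian features. The
# generator exists so that every downstream stage (oversampling, graph
# construction, training, evaluation) is exercisable without any external
# download; it reproduces the study-cohort class counts and a controllable
# degree of class separability, not the physics of fMRI co-activation.

#' Specify one synthetic class
#'
#' @param label a brain-state label (see [state_labels()]).
#' @param count number of samples to draw (>= 1).
#' @param mean 6-vector of class feature means (canonical feature order).
#' @param covariance 6x6 symmetric positive-semidefinite covariance;
#'   scalars are expanded to `scalar * I`.
#' @return a `class_spec` object.
#' @export
class_spec <- function(label, count, mean = rep(0, 6), covariance = 1) {
  if (!is.character(label) || length(label) != 1 ||
      !(label %in% state_labels())) {
    stop("label must be one of: ", paste(state_labels(), collapse = ", "))
  }
  stopifnot(count >= 1, length(mean) == 6, all(is.finite(mean)))
  if (length(covariance) == 1) covariance <- diag(6) * covariance
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8))) {
    stop("covariance must be symmetric")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance must be positive semi-definite")
  }
  structure(list(label = label, count = as.integer(count),
                 mean = as.numeric(mean), covariance = covariance),
            class = "class_spec")
}

#' Specify a synthetic cohort
#'
#' `separation` rescales the spread of the class means about their common
#' centroid: 0 collapses all class means onto the centroid (no class
#' signal), larger values move them apart proportionally.
#'
#' @param classes list of [class_spec] objects with distinct labels.
#' @param seed integer driving one deterministic generator; per-class
#'   streams are derived from it so adding a class does not perturb the
#'   draws of earlier classes.
#' @param separation nonnegative scale on the spread of class means.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(classes, seed = 1L, separation = 1) {
  stopifnot(is.list(classes), length(classes) >= 1, separation >= 0)
  for (cl in classes) stopifnot(inherits(cl, "class_spec"))
  labs <- vapply(classes, function(cl) cl$label, character(1))
  if (anyDuplicated(labs)) stop("class labels must be distinct")
  structure(list(classes = classes, seed = as.integer(seed),
                 separation = separation),
            class = "cohort_spec")
}

# Deterministic derivation of sub-seeds from one master seed; keeps values
# inside the 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, offset) {
  v <- (as.double(seed) %% 2147483647) * 48271 + as.double(offset)
  as.integer(v %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws each class's records from its Gaussian after rescaling the class
#' means about their centroid by `separation`. Identical specs and seeds
#' give bit-identical tables.
#'
#' @param spec a [cohort_spec].
#' @return a [sample_table]; synthetic records carry the source tag
#'   `"synthetic"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mu <- t(vapply(spec$classes, function(cl) cl$mean, numeric(6)))
  center <- colMeans(mu)
  parts <- vector("list", length(spec$classes))
  for (i in seq_along(spec$classes)) {
    cl <- spec$classes[[i]]
    eff_mean <- center + spec$separation * (mu[i, ] - center)
    set.seed(derive_seed(spec$seed, 1000L + i))
    x <- MASS::mvrnorm(n = cl$count, mu = eff_mean, Sigma = cl$covariance)
    x <- matrix(x, nrow = cl$count, ncol = 6,
                dimnames = list(NULL, feature_names()))
    parts[[i]] <- data.frame(x, label = cl$label,
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, parts)
  sample_table(df[feature_names()], label = df$label,
               source_tag = "synthetic")
}

# Fixed, well-spread unit directions in feature space for up to 10 classes:
# signed binary codes over the 6 features, normalized to unit length. Each
# class gets a distinct feature-rank profile, which is what the Spearman
# similarity graph keys on.
class_mean_directions <- function(k) {
  codes <- rbind(
    c( 1, -1, -1, -1, -1, -1),
    c(-1,  1, -1, -1, -1, -1),
    c(-1, -1,  1, -1, -1, -1),
    c(-1, -1, -1,  1, -1, -1),
    c(-1, -1, -1, -1,  1, -1),
    c(-1, -1, -1, -1, -1,  1),
    c( 1,  1, -1, -1, -1, -1),
    c(-1, -1,  1,  1, -1, -1),
    c(-1, -1, -1, -1,  1,  1),
    c( 1, -1,  1, -1,  1, -1))
  codes <- codes / sqrt(rowSums(codes^2))
  codes[seq_len(k), , drop = FALSE]
}

#' Counts of the eight-state study cohort
#'
#' Per-class record counts of the merged eight-state cohort before and
#' after SMOTE augmentation: W 78, DS 23, N3 54, UWS 55, REM 7, N2 37,
#' BI 15, HC 21 (290 samples) growing to 187, 141, 190, 164, 107, 154,
#' 117, 137 (1197 samples).
#'
#' @return named integer vector of per-class counts.
#' @export
cohort_counts <- function() {
  c(W = 78L, DS = 23L, N3 = 54L, UWS = 55L, REM = 7L, N2 = 37L,
    BI = 15L, HC = 21L)
}

#' @rdname cohort_counts
#' @export
smote_targets <- function() {
  c(W = 187L, DS = 141L, N3 = 190L, UWS = 164L, REM = 107L, N2 = 154L,
    BI = 117L, HC = 137L)
}

#' Synthetic stand-in for the eight-state study cohort
#'
#' Generates a 290-sample cohort with exactly the study's pre-augmentation
#' class counts ([cohort_counts()]). Class means sit on fixed unit
#' directions scaled by `separation` over unit covariance, so classes are
#' well separated for `separation >= 5` and indistinguishable at 0.
#'
#' @param seed integer seed.
#' @param separation nonnegative class-separation scale.
#' @return a 290-record [sample_table].
#' @export
anesthesia_cohort <- function(seed = 1L, separation = 5) {
  counts <- cohort_counts()
  dirs <- class_mean_directions(length(counts))
  classes <- lapply(seq_along(counts), function(i) {
    class_spec(names(counts)[i], counts[i], mean = dirs[i, ],
               covariance = 1)
  })
  generate_cohort(cohort_spec(classes, seed = seed,
                              separation = separation))
}

#' Design of the extended ten-state cohort
#'
#' The extended experiment merges 14 sub-datasets (7 brain-state contrasts,
#' each extracted with global-signal co-activation and with random-point
#' sampling) spanning 10 labels, 872 samples in total; the per-class
#' augmentation subtotals sum to 1195.
#'
#' @return `extended_cohort_design()`: a data frame with one row per
#'   sub-dataset and one column per label holding record counts;
#'   `extended_smote_targets()`: named integer vector of post-augmentation
#'   per-class targets.
#' @export
extended_cohort_design <- function() {
  m <- rbind(
    WvsDS_GScoactivation    = c(30, 23,  0,  0,  0,  0, 0,  0,  0,  0),
    WvsDS_random_point      = c(30, 23,  0,  0,  0,  0, 0,  0,  0,  0),
    EOvsEC_GScoactivation   = c( 0,  0, 67, 67,  0,  0, 0,  0,  0,  0),
    EOvsEC_random_point     = c( 0,  0, 67, 67,  0,  0, 0,  0,  0,  0),
    N3vsUWS_GScoactivation  = c( 0,  0,  0,  0, 10, 36, 0,  0,  0,  0),
    N3vsUWS_random_point    = c( 0,  0,  0,  0, 18, 36, 0,  0,  0,  0),
    REMvsWvsN3_GScoactivation = c(19, 0,  0,  0, 10,  0, 7,  0,  0,  0),
    REMvsWvsN3_random_point = c(19,  0,  0,  0, 10,  0, 7,  0,  0,  0),
    WvsN2vsN3_GScoactivation = c(30, 0,  0,  0, 18,  0, 0, 37,  0,  0),
    WvsN2vsN3_random_point  = c(30,  0,  0,  0, 18,  0, 0, 37,  0,  0),
    BIvsUWS_GScoactivation  = c(15,  0,  0,  0,  0, 19, 0,  0,  0,  0),
    BIvsUWS_random_point    = c(15,  0,  0,  0,  0, 19, 0,  0,  0,  0),
    HCvsUWS_GScoactivation  = c( 0,  0,  0,  0,  0, 19, 0,  0,  0, 21),
    HCvsUWS_random_point    = c( 0,  0,  0,  0,  0, 19, 0,  0,  8, 21))
  colnames(m) <- state_labels()
  as.data.frame(m)
}

#' @rdname extended_cohort_design
#' @export
extended_smote_targets <- function() {
  c(W = 217L, DS = 63L, EO = 184L, EC = 184L, N3 = 126L, UWS = 203L,
    REM = 19L, N2 = 101L, BI = 41L, HC = 57L)
}

#' Synthetic stand-in for the extended ten-state cohort
#'
#' Builds the 14 sub-tables of [extended_cohort_design()] (872 records over
#' 10 labels) and merges them; source tags name the sub-dataset.
#'
#' @inheritParams anesthesia_cohort
#' @return an 872-record [sample_table].
#' @export
extended_cohort <- function(seed = 1L, separation = 5) {
  merge_tables(extended_subtables(seed = seed, separation = separation))
}

#' @rdname extended_cohort
#' @export
extended_subtables <- function(seed = 1L, separation = 5) {
  design <- extended_cohort_design()
  dirs <- class_mean_directions(ncol(design))
  tables <- vector("list", nrow(design))
  for (d in seq_len(nrow(design))) {
    counts <- unlist(design[d, ])
    present <- which(counts > 0)
    classes <- lapply(present, function(i) {
      class_spec(colnames(design)[i], counts[i], mean = dirs[i, ],
                 covariance = 1)
    })
    tab <- generate_cohort(cohort_spec(classes,
                                       seed = derive_seed(seed, 37L * d),
                                       separation = separation))
    tab$source_tag <- rownames(design)[d]
    tables[[d]] <- tab
  }
  tables
}
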
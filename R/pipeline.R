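# End-to-end orchestration: load or simulate a cohort, optionally
# oversample, build and threshold the similarity graph, split, train,
# evaluate, and log enough provenance to regenerate every artifact
# bit-identically. One top-level seed expands deterministically into the
# per-stage seeds (simulation, oversampling, split, training).

#' Configure a pipeline run
#'
#' @param data `"study"` (default; the synthetic eight-state 290-sample
#'   cohort), `"extended"` (the ten-state 872-sample cohort), a file path
#'   to a sample table, or a [sample_table] object.
#' @param oversample `"smote"` (default), `"random"` or `"none"`.
#' @param targets per-class post-augmentation counts; defaults to
#'   [smote_targets()] for the study cohort and
#'   [extended_smote_targets()] for the extended cohort (required for
#'   file/table data when oversampling).
#' @param k_neighbors SMOTE neighborhood size (default 5).
#' @param edge_method `"spearman"` (default), `"cosine"` or
#'   `"euclidean"`.
#' @param tau edge-weight threshold; edges with weight <= `tau` are kept
#'   (default 1, i.e. all edges for correlation-bounded weights).
#' @param gnn named list of [gnn_config()] overrides (all but
#'   `num_classes`, which is derived from the data).
#' @param train named list of [train_config()] overrides (all but
#'   `seed`).
#' @param train_fraction training share of the stratified split
#'   (default 0.8).
#' @param separation class-separation scale of the synthetic cohorts
#'   (default 5).
#' @param seed single master seed expanded into all stage seeds.
#' @param outdir directory for artifacts, or `NULL` to skip writing.
#' @return a `run_config` object.
#' @export
run_config <- function(data = "study", oversample = "smote",
                       targets = NULL, k_neighbors = 5L,
                       edge_method = "spearman", tau = 1.0,
                       gnn = list(), train = list(),
                       train_fraction = 0.8, separation = 5,
                       seed = 1L, outdir = NULL) {
  stopifnot(oversample %in% c("smote", "random", "none"),
            edge_method %in% c("spearman", "cosine", "euclidean"),
            train_fraction > 0, train_fraction < 1)
  if (is.character(data) && length(data) == 1 &&
      !data %in% c("study", "extended") && !file.exists(data)) {
    stop("data file not found: ", data)
  }
  structure(list(data = data, oversample = oversample, targets = targets,
                 k_neighbors = as.integer(k_neighbors),
                 edge_method = edge_method, tau = tau, gnn = gnn,
                 train = train, train_fraction = train_fraction,
                 separation = separation, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

run_seeds <- function(config) {
  list(simulate = derive_seed(config$seed, 1L),
       oversample = derive_seed(config$seed, 2L),
       split = derive_seed(config$seed, 3L),
       train = derive_seed(config$seed, 4L))
}

pipeline_table <- function(config, seeds) {
  d <- config$data
  if (inherits(d, "sample_table")) return(d)
  if (identical(d, "study")) {
    return(anesthesia_cohort(seed = seeds$simulate,
                             separation = config$separation))
  }
  if (identical(d, "extended")) {
    return(extended_cohort(seed = seeds$simulate,
                           separation = config$separation))
  }
  read_sample_table(d)
}

default_targets <- function(config) {
  if (!is.null(config$targets)) return(config$targets)
  if (identical(config$data, "study")) return(smote_targets())
  if (identical(config$data, "extended")) return(extended_smote_targets())
  stop("oversampling a file/table data source requires explicit targets")
}

pipeline_augment <- function(table, config, seeds) {
  switch(config$oversample,
    none = table,
    smote = smote(table, oversample_spec(default_targets(config),
                                         k_neighbors = config$k_neighbors,
                                         seed = seeds$oversample)),
    random = random_oversample(table, default_targets(config),
                               seed = seeds$oversample))
}

pipeline_model_configs <- function(config, num_classes) {
  gnn_args <- c(list(num_classes = num_classes), config$gnn)
  train_args <- c(config$train, list(seed = NULL))
  train_args$seed <- NULL
  list(gnn = do.call(gnn_config, gnn_args),
       train = do.call(train_config,
                       c(train_args, list(seed = run_seeds(config)$train))))
}

evaluate_split <- function(graph, state, mask) {
  pred <- predict(state, graph)
  metric_panel(confusion_matrix(as.character(graph$labels[mask]),
                                as.character(pred[mask]),
                                label_order = levels(graph$labels)))
}

# Polynomial hash over the serialized configuration (output directory
# excluded: it is not part of the scientific configuration); enough to
# tie artifacts to the config that produced them.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full classification pipeline
#'
#' Executes load/simulate, optional oversampling, edge construction,
#' thresholding, the stratified split, training and evaluation. With an
#' `outdir` the sample table, edge table, training history, metrics
#' report and a provenance log (stage seeds, record/edge counts, config
#' hash) are written; repeated runs with an identical config produce
#' bit-identical artifacts.
#'
#' @param config a [run_config].
#' @return list with `report` (test-set `metrics_report`),
#'   `train_report`, `history`, `state`, `graph`, `table`, `edges` and
#'   `seeds`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- run_seeds(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  table <- stage("data", pipeline_table(config, seeds))
  table <- stage("oversample", pipeline_augment(table, config, seeds))
  edges_all <- stage("edges",
                     pairwise_edge_table(table, config$edge_method))
  edges <- stage("threshold", threshold_filter(edges_all, config$tau))
  graph <- stage("split",
                 assemble_graph(table, edges, config$train_fraction,
                                split_seed = seeds$split))
  mc <- pipeline_model_configs(config, nlevels(graph$labels))
  fit <- stage("train", train_gnn(graph, mc$gnn, mc$train))
  report <- stage("evaluate",
                  evaluate_split(graph, fit$state, graph$test_mask))
  train_report <- stage("evaluate",
                        evaluate_split(graph, fit$state, graph$train_mask))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_sample_table(table, file.path(config$outdir, "sample_table.csv"))
    write_edge_table(edges, file.path(config$outdir, "edge_table.csv"))
    write.csv(fit$history, file.path(config$outdir, "history.csv"),
              row.names = FALSE)
    write_metrics_report(report, config$outdir)
    prov <- list(seeds = seeds,
                 config_hash = config_hash(config),
                 n_samples = nrow(table),
                 n_edges_total = nrow(edges_all),
                 n_edges_kept = nrow(edges),
                 n_train = sum(graph$train_mask),
                 n_test = sum(graph$test_mask),
                 edge_method = config$edge_method,
                 tau = config$tau,
                 oversample = config$oversample)
    yaml::write_yaml(prov, file.path(config$outdir, "provenance.yaml"))
  }
  list(report = report, train_report = train_report,
       history = fit$history, state = fit$state, graph = graph,
       table = table, edges = edges, seeds = seeds, config = config)
}

#' Default greedy ablation plan
#'
#' The eight hyperparameter axes of the tuning study, in sweep order:
#' conv layers 1-5, hidden units (64,64)/(32,32), combination
#' concat/recurrent, activation elu/relu/tanh/softmax, optimizer
#' adam/nadam/adamax/sgd, learning rate 0.01/0.001/0.0001/0.0007,
#' dropout 0.2-0.7, batch size 32/64/128.
#'
#' @return named list mapping axis name to candidate values.
#' @export
ablation_plan <- function() {
  list(conv_layers = as.list(1:5),
       hidden_units = list(c(64L, 64L), c(32L, 32L)),
       combination = list("concat", "recurrent"),
       activation = list("elu", "relu", "tanh", "softmax"),
       optimizer = list("adam", "nadam", "adamax", "sgd"),
       learning_rate = list(0.01, 0.001, 0.0001, 0.0007),
       dropout = list(0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
       batch_size = list(32L, 64L, 128L))
}

set_axis <- function(config, axis, value) {
  switch(axis,
    conv_layers = {
      hu <- config$gnn$hidden_units
      base_unit <- if (is.null(hu)) 32L else hu[1]
      config$gnn$num_conv_layers <- value
      config$gnn$hidden_units <- rep(base_unit, value)
    },
    hidden_units = {
      config$gnn$hidden_units <- value
      config$gnn$num_conv_layers <- length(value)
    },
    combination = config$gnn$combination <- value,
    activation = config$gnn$activation <- value,
    dropout = config$gnn$dropout_rate <- value,
    optimizer = config$train$optimizer <- value,
    learning_rate = config$train$learning_rate <- value,
    batch_size = config$train$batch_size <- value,
    stop("unknown ablation axis: ", axis))
  config
}

#' Greedy sequential hyperparameter ablation
#'
#' Sweeps the axes in plan order; within an axis every candidate is run
#' with all other settings frozen, the best candidate (highest test
#' accuracy, ties to the first listed) is frozen into the base config
#' before the next axis. Selecting on test accuracy mirrors the original
#' tuning protocol and is optimistically biased; pass a config whose
#' split is a validation split if that bias matters. Failed runs are
#' recorded with `NA` accuracy and the sweep continues.
#'
#' @param plan named list of candidate values per axis (see
#'   [ablation_plan()]).
#' @param base a [run_config].
#' @return data frame with columns `axis`, `candidate`, `test_accuracy`,
#'   `selected`.
#' @export
greedy_ablation <- function(plan, base) {
  stopifnot(is.list(plan), length(plan) >= 1, inherits(base, "run_config"))
  rows <- list()
  for (axis in names(plan)) {
    cands <- plan[[axis]]
    accs <- rep(NA_real_, length(cands))
    for (i in seq_along(cands)) {
      cfg <- set_axis(base, axis, cands[[i]])
      res <- tryCatch(run_pipeline(cfg), error = function(e) NULL)
      if (!is.null(res)) accs[i] <- res$report$accuracy
    }
    if (all(is.na(accs))) {
      best <- 1L
    } else {
      best <- which.max(accs)  # first maximum wins ties
      base <- set_axis(base, axis, cands[[best]])
    }
    rows[[axis]] <- data.frame(
      axis = axis,
      candidate = vapply(cands, function(v) paste(v, collapse = ","),
                         character(1)),
      test_accuracy = accs,
      selected = seq_along(cands) == best)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "final_config") <- base
  out
}

#' Threshold sweep
#'
#' Builds the cohort and edge weights once, then for each threshold
#' filters, splits, trains and evaluates. Edge counts are exact and
#' monotone non-decreasing in `tau`.
#'
#' @param base a [run_config].
#' @param taus numeric vector of thresholds (default the study's sweep:
#'   0.7, 0.8, 0.9, 0.93, 0.97, 1).
#' @return data frame with columns `tau`, `edges`, `test_accuracy`.
#' @export
threshold_sweep <- function(base,
                            taus = c(0.7, 0.8, 0.9, 0.93, 0.97, 1.0)) {
  stopifnot(inherits(base, "run_config"), length(taus) >= 1)
  seeds <- run_seeds(base)
  table <- pipeline_table(base, seeds)
  table <- pipeline_augment(table, base, seeds)
  edges_all <- pairwise_edge_table(table, base$edge_method)
  out <- data.frame(tau = taus, edges = NA_integer_,
                    test_accuracy = NA_real_)
  for (i in seq_along(taus)) {
    edges <- threshold_filter(edges_all, taus[i])
    out$edges[i] <- nrow(edges)
    graph <- assemble_graph(table, edges, base$train_fraction,
                            split_seed = seeds$split)
    mc <- pipeline_model_configs(base, nlevels(graph$labels))
    fit <- train_gnn(graph, mc$gnn, mc$train)
    rep <- evaluate_split(graph, fit$state, graph$test_mask)
    out$test_accuracy[i] <- rep$accuracy
  }
  out
}

#' Compare edge-weighting methods
#'
#' Three runs differing only in the edge-weight method (Spearman, cosine,
#' Euclidean), identical seeds and settings elsewhere.
#'
#' @param base a [run_config].
#' @return data frame with columns `method`, `test_accuracy`.
#' @export
compare_edge_methods <- function(base) {
  stopifnot(inherits(base, "run_config"))
  methods <- c("spearman", "cosine", "euclidean")
  acc <- vapply(methods, function(m) {
    cfg <- base
    cfg$edge_method <- m
    run_pipeline(cfg)$report$accuracy
  }, numeric(1))
  data.frame(method = methods, test_accuracy = unname(acc))
}

#' Compare oversampling arms
#'
#' Runs the pipeline without augmentation, with random duplication and
#' with SMOTE, sharing all seeds and downstream settings.
#'
#' @param base a [run_config].
#' @return data frame with columns `arm`, `n_samples`, `test_accuracy`.
#' @export
compare_oversampling <- function(base) {
  stopifnot(inherits(base, "run_config"))
  arms <- c("none", "random", "smote")
  rows <- lapply(arms, function(a) {
    cfg <- base
    cfg$oversample <- a
    res <- run_pipeline(cfg)
    data.frame(arm = a, n_samples = nrow(res$table),
               test_accuracy = res$report$accuracy)
  })
  do.call(rbind, rows)
}
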
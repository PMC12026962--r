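# The message-passing node classifier. Topology:
#
#   features -> FFN block -> FFN block            (preprocess)
#            -> conv layer 1 (+ additive skip)
#            -> conv layer 2 (+ additive skip)
#            -> FFN block -> FFN block + skip     (postprocess, residual)
#            -> dense -> softmax
#
# i.e. four FFN blocks and three skip connections in total (two bridging
# the conv layers, one inside the postprocess stack). Each conv layer
# aggregates neighbor states (sum / mean / elementwise max, optionally
# edge-weighted) and combines the message with the node's own state,
# either by concatenation + dense ("concat", equivalent to
# sigma(A F W_neighbour + F W_self) under sum aggregation) or by a gated
# update ("recurrent"). Message passing always uses the full graph;
# mini-batches only select the nodes contributing to the loss.

#' Configure the message-passing classifier
#'
#' @param num_classes number of brain-state classes (output width).
#' @param num_conv_layers number of message-passing layers (default 2).
#' @param hidden_units integer vector of per-conv-layer widths, one entry
#'   per layer (default `c(32, 32)`); also sets the preprocess width.
#' @param aggregation neighbor aggregation: `"max"` (default), `"sum"` or
#'   `"mean"`.
#' @param combination how the neighbor message joins the node state:
#'   `"concat"` (default) or `"recurrent"` (gated update).
#' @param recurrent_activation gate nonlinearity for the recurrent
#'   combination: `"softplus"` (default), `"sigmoid"` or `"tanh"`.
#' @param activation hidden nonlinearity: `"elu"` (default), `"relu"`,
#'   `"tanh"` or `"softmax"`.
#' @param dropout_rate dropout rate of the FFN blocks (default 0.3).
#' @param use_edge_weights logical; if `TRUE` neighbor states are scaled
#'   by the edge weight before aggregation, otherwise only the topology
#'   is used (default `FALSE`).
#' @param input_dropout logical; if `FALSE` (default) the first FFN
#'   block — the one acting on the raw six-feature input — skips its
#'   dropout layer. With so few input features, input dropout deletes a
#'   large share of the measured signal on every step and prevents the
#'   model from fitting even cleanly separable cohorts; hidden blocks
#'   always keep `dropout_rate`.
#' @return a `gnn_config` object.
#' @export
gnn_config <- function(num_classes, num_conv_layers = 2L,
                       hidden_units = c(32L, 32L), aggregation = "max",
                       combination = "concat",
                       recurrent_activation = "softplus",
                       activation = "elu", dropout_rate = 0.3,
                       use_edge_weights = FALSE, input_dropout = FALSE) {
  stopifnot(num_classes >= 2, num_conv_layers >= 1,
            all(hidden_units >= 1),
            aggregation %in% c("sum", "mean", "max"),
            combination %in% c("concat", "recurrent"),
            recurrent_activation %in% c("softplus", "sigmoid", "tanh"),
            activation %in% c("elu", "relu", "tanh", "softmax"),
            dropout_rate >= 0, dropout_rate < 1,
            is.logical(use_edge_weights), is.logical(input_dropout))
  if (length(hidden_units) != num_conv_layers) {
    stop("hidden_units must have one entry per conv layer")
  }
  structure(list(num_classes = as.integer(num_classes),
                 num_conv_layers = as.integer(num_conv_layers),
                 hidden_units = as.integer(hidden_units),
                 aggregation = aggregation, combination = combination,
                 recurrent_activation = recurrent_activation,
                 activation = activation, dropout_rate = dropout_rate,
                 use_edge_weights = use_edge_weights,
                 input_dropout = input_dropout),
            class = "gnn_config")
}

#' Configure training
#'
#' Defaults follow the tuned setup: SGD, learning rate 0.01, batch size
#' 64, 400 epochs.
#'
#' @param optimizer `"sgd"` (default), `"adam"`, `"nadam"` or `"adamax"`.
#' @param learning_rate positive step size (default 0.01).
#' @param batch_size training-node mini-batch size (default 64).
#' @param epochs number of passes over the training nodes (default 400;
#'   0 returns the freshly initialized model).
#' @param seed integer seed driving initialization, shuffling and dropout.
#' @return a `train_config` object.
#' @export
train_config <- function(optimizer = "sgd", learning_rate = 0.01,
                         batch_size = 64L, epochs = 400L, seed = 1L) {
  stopifnot(optimizer %in% c("sgd", "adam", "nadam", "adamax"),
            learning_rate > 0, batch_size >= 1, epochs >= 0)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

agg_type_code <- function(aggregation) {
  match(aggregation, c("sum", "mean", "max"))
}

ffn_cfg <- function(units, config) {
  ffn_block_config(units, config$dropout_rate, config$activation)
}

# Parameter layout: one flat named list keyed "<layer>.<tensor>"; running
# batch-norm moments live in a parallel flat list (not touched by the
# optimizer).
gnn_init <- function(input_dim, config, seed = 1L) {
  set.seed(derive_seed(seed, 11L))
  params <- list()
  running <- list()
  add_block <- function(prefix, in_dim, units) {
    st <- ffn_block_init(in_dim, ffn_block_config(units))
    params[[paste0(prefix, ".gamma")]] <<- st$gamma
    params[[paste0(prefix, ".beta")]] <<- st$beta
    params[[paste0(prefix, ".W")]] <<- st$W
    params[[paste0(prefix, ".b")]] <<- st$b
    running[[paste0(prefix, ".mean")]] <<- st$mean
    running[[paste0(prefix, ".var")]] <<- st$var
  }
  dense_init <- function(in_dim, out_dim) {
    limit <- sqrt(6 / in_dim)
    matrix(runif(in_dim * out_dim, -limit, limit), in_dim, out_dim)
  }
  h1 <- config$hidden_units[1]
  add_block("pre1", input_dim, h1)
  add_block("pre2", h1, h1)
  in_dim <- h1
  for (l in seq_len(config$num_conv_layers)) {
    out_dim <- config$hidden_units[l]
    p <- paste0("conv", l)
    params[[paste0(p, ".W")]] <- dense_init(2 * in_dim, out_dim)
    params[[paste0(p, ".b")]] <- rep(0, out_dim)
    if (config$combination == "recurrent") {
      params[[paste0(p, ".Wg")]] <- dense_init(2 * in_dim, out_dim)
      params[[paste0(p, ".bg")]] <- rep(0, out_dim)
    }
    if (in_dim != out_dim) {
      params[[paste0(p, ".P")]] <- dense_init(in_dim, out_dim)
    }
    in_dim <- out_dim
  }
  add_block("post1", in_dim, in_dim)
  add_block("post2", in_dim, in_dim)
  params[["out.W"]] <- dense_init(in_dim, config$num_classes)
  params[["out.b"]] <- rep(0, config$num_classes)
  structure(list(params = params, running = running, config = config,
                 input_dim = input_dim),
            class = "gnn_state")
}

block_pars <- function(state, prefix) {
  list(gamma = state$params[[paste0(prefix, ".gamma")]],
       beta = state$params[[paste0(prefix, ".beta")]],
       W = state$params[[paste0(prefix, ".W")]],
       b = state$params[[paste0(prefix, ".b")]],
       mean = state$running[[paste0(prefix, ".mean")]],
       var = state$running[[paste0(prefix, ".var")]])
}

#' Aggregate neighbor states
#'
#' Row `i` of the result is the sum, mean or elementwise max of
#' `w(i, v) * state_v` over the neighbors `v` of node `i` (`w == 1` when
#' `use_edge_weights` is `FALSE`). Nodes without neighbors receive the
#' zero vector.
#'
#' @param node_states numeric matrix (n x h).
#' @param edges an `edge_list` with endpoints in `1..n`.
#' @param aggregation `"sum"`, `"mean"` or `"max"`.
#' @param use_edge_weights logical.
#' @return numeric matrix (n x h).
#' @export
aggregate_neighbors <- function(node_states, edges,
                                aggregation = c("sum", "mean", "max"),
                                use_edge_weights = FALSE) {
  aggregation <- match.arg(aggregation)
  node_states <- as.matrix(node_states)
  stopifnot(inherits(edges, "edge_list"))
  if (nrow(edges) > 0 && max(edges$source) > nrow(node_states)) {
    stop("edge endpoints outside 1..", nrow(node_states))
  }
  from <- c(edges$target, edges$source) - 1L
  to <- c(edges$source, edges$target) - 1L
  w <- if (use_edge_weights) rep(edges$weight, 2) else rep(1, 2 * nrow(edges))
  agg_forward_cpp(node_states, from, to, w, agg_type_code(aggregation))$out
}

conv_forward_core <- function(h, de, pars, config, training = FALSE) {
  w <- if (config$use_edge_weights) de$w else rep(1, length(de$from))
  type <- agg_type_code(config$aggregation)
  agg <- agg_forward_cpp(h, de$from, de$to, w, type)
  Z <- cbind(h, agg$out)
  lin <- sweep(Z %*% pars$W, 2, pars$b, "+")
  if (config$combination == "concat") {
    out <- act_forward(config$activation, lin)
    cache <- list(h = h, agg = agg, Z = Z, lin = lin, out = out, w = w,
                  type = type)
  } else {
    cand <- act_forward(config$activation, lin)
    ling <- sweep(Z %*% pars$Wg, 2, pars$bg, "+")
    gate <- act_forward(config$recurrent_activation, ling)
    out <- gate * cand
    cache <- list(h = h, agg = agg, Z = Z, lin = lin, cand = cand,
                  ling = ling, gate = gate, out = out, w = w, type = type)
  }
  list(out = out, cache = cache)
}

conv_backward_core <- function(g, cache, pars, config, de) {
  if (config$combination == "concat") {
    glin <- act_backward(config$activation, g, cache$lin, cache$out)
    gZ <- tcrossprod(glin, pars$W)
    grads <- list(W = crossprod(cache$Z, glin), b = colSums(glin))
  } else {
    gcand <- g * cache$gate
    ggate <- g * cache$cand
    glin <- act_backward(config$activation, gcand, cache$lin, cache$cand)
    gling <- act_backward(config$recurrent_activation, ggate, cache$ling,
                          cache$gate)
    gZ <- tcrossprod(glin, pars$W) + tcrossprod(gling, pars$Wg)
    grads <- list(W = crossprod(cache$Z, glin), b = colSums(glin),
                  Wg = crossprod(cache$Z, gling), bg = colSums(gling))
  }
  hw <- ncol(cache$h)
  gself <- gZ[, seq_len(hw), drop = FALSE]
  gmsg <- gZ[, hw + seq_len(hw), drop = FALSE]
  gh <- gself + agg_backward_cpp(gmsg, de$from, de$to, cache$w,
                                 cache$type, cache$agg$argmax,
                                 cache$agg$deg)
  list(gh = gh, grads = grads)
}

#' Apply one message-passing layer
#'
#' Aggregates neighbor states and combines the message with the node's
#' own state per the configured combination, then applies the
#' nonlinearity. With sum aggregation, unit weights and the concat
#' combination this is exactly
#' `sigma(A %*% F %*% W_neighbour + F %*% W_self)` with the dense matrix
#' partitioned as `rbind(W_self, W_neighbour)`.
#'
#' @param node_states numeric matrix (n x h).
#' @param edges an `edge_list`.
#' @param layer_state list with `W` (2h x h') and `b` (and `Wg`, `bg` for
#'   the recurrent combination).
#' @param config a [gnn_config].
#' @return numeric matrix (n x h').
#' @export
conv_layer <- function(node_states, edges, layer_state, config) {
  node_states <- as.matrix(node_states)
  stopifnot(inherits(edges, "edge_list"), inherits(config, "gnn_config"))
  de <- list(from = c(edges$target, edges$source) - 1L,
             to = c(edges$source, edges$target) - 1L,
             w = rep(edges$weight, 2))
  conv_forward_core(node_states, de, layer_state, config)$out
}

gnn_forward_full <- function(graph, state, mode = "eval") {
  config <- state$config
  training <- identical(mode, "train")
  de <- directed_edges(graph)
  h1 <- config$hidden_units[1]
  hl <- config$hidden_units[config$num_conv_layers]
  caches <- list()
  running <- state$running

  run_block <- function(x, prefix, units) {
    cfg <- ffn_cfg(units, config)
    if (prefix == "pre1" && !isTRUE(config$input_dropout)) {
      cfg$dropout_rate <- 0
    }
    step <- ffn_block_core(x, block_pars(state, prefix), cfg, mode)
    running[[paste0(prefix, ".mean")]] <<- step$running$mean
    running[[paste0(prefix, ".var")]] <<- step$running$var
    caches[[prefix]] <<- step$cache
    step$out
  }

  h <- run_block(graph$features, "pre1", h1)
  h <- run_block(h, "pre2", h1)
  for (l in seq_len(config$num_conv_layers)) {
    p <- paste0("conv", l)
    pars <- list(W = state$params[[paste0(p, ".W")]],
                 b = state$params[[paste0(p, ".b")]],
                 Wg = state$params[[paste0(p, ".Wg")]],
                 bg = state$params[[paste0(p, ".bg")]])
    step <- conv_forward_core(h, de, pars, config, training)
    P <- state$params[[paste0(p, ".P")]]
    carried <- if (is.null(P)) h else h %*% P
    caches[[p]] <- step$cache
    h <- step$out + carried
  }
  q1 <- run_block(h, "post1", hl)
  p2 <- run_block(q1, "post2", hl)
  q <- q1 + p2
  logits <- sweep(q %*% state$params[["out.W"]], 2,
                  state$params[["out.b"]], "+")
  probs <- row_softmax(logits)
  list(probs = probs, logits = logits, q = q, q1 = q1, caches = caches,
       running = running, de = de)
}

gnn_backward_full <- function(glogits, fwd, state) {
  config <- state$config
  grads <- list()
  add_grads <- function(prefix, g) {
    for (nm in names(g)) grads[[paste0(prefix, ".", nm)]] <<- g[[nm]]
  }
  grads[["out.W"]] <- crossprod(fwd$q, glogits)
  grads[["out.b"]] <- colSums(glogits)
  gq <- tcrossprod(glogits, state$params[["out.W"]])

  hl <- config$hidden_units[config$num_conv_layers]
  bk2 <- ffn_block_backward(gq, fwd$caches[["post2"]],
                            block_pars(state, "post2"),
                            ffn_cfg(hl, config))
  add_grads("post2", bk2$grads)
  gq1 <- gq + bk2$gx
  bk1 <- ffn_block_backward(gq1, fwd$caches[["post1"]],
                            block_pars(state, "post1"),
                            ffn_cfg(hl, config))
  add_grads("post1", bk1$grads)
  gh <- bk1$gx

  for (l in rev(seq_len(config$num_conv_layers))) {
    p <- paste0("conv", l)
    pars <- list(W = state$params[[paste0(p, ".W")]],
                 Wg = state$params[[paste0(p, ".Wg")]])
    bk <- conv_backward_core(gh, fwd$caches[[p]], pars, config, fwd$de)
    P <- state$params[[paste0(p, ".P")]]
    if (is.null(P)) {
      gcarried <- gh
    } else {
      bk$grads$P <- crossprod(fwd$caches[[p]]$h, gh)
      gcarried <- tcrossprod(gh, P)
    }
    add_grads(p, bk$grads)
    gh <- bk$gh + gcarried
  }
  h1 <- config$hidden_units[1]
  bkp2 <- ffn_block_backward(gh, fwd$caches[["pre2"]],
                             block_pars(state, "pre2"),
                             ffn_cfg(h1, config))
  add_grads("pre2", bkp2$grads)
  bkp1 <- ffn_block_backward(bkp2$gx, fwd$caches[["pre1"]],
                             block_pars(state, "pre1"),
                             ffn_cfg(h1, config))
  add_grads("pre1", bkp1$grads)
  grads
}

#' Forward pass of the classifier
#'
#' @param graph a `graph_dataset` (see [assemble_graph()]).
#' @param state a `gnn_state` (see [train_gnn()]).
#' @param config the model configuration; defaults to the one stored in
#'   `state`.
#' @param training logical; evaluation mode (default) is deterministic.
#' @return n x K matrix of class probabilities (rows sum to 1).
#' @export
gnn_forward <- function(graph, state, config = state$config,
                        training = FALSE) {
  stopifnot(inherits(graph, "graph_dataset"), inherits(state, "gnn_state"))
  if (config$num_classes != nlevels(graph$labels)) {
    stop("configuration error: model has ", config$num_classes,
         " classes but the graph has ", nlevels(graph$labels))
  }
  state$config <- config
  gnn_forward_full(graph, state, if (training) "train" else "eval")$probs
}

masked_ce <- function(probs, y_int, mask) {
  idx <- which(mask)
  p <- probs[cbind(idx, y_int[idx])]
  -mean(log(pmax(p, 1e-12)))
}

masked_acc <- function(probs, y_int, mask) {
  idx <- which(mask)
  pred <- apply(probs[idx, , drop = FALSE], 1, which.max)
  mean(pred == y_int[idx])
}

#' Train the classifier
#'
#' Minimizes softmax cross-entropy over the training-mask nodes. Each
#' epoch shuffles the training nodes into mini-batches; every step runs a
#' full-graph forward pass (message passing is never subsampled) and
#' computes the loss on the batch nodes only. Deterministic for a fixed
#' seed.
#'
#' @param graph a `graph_dataset` with a non-empty training mask.
#' @param config a [gnn_config] (its `num_classes` must match the graph).
#' @param tc a [train_config].
#' @return list with elements `state` (a `gnn_state`, including the label
#'   levels) and `history` (data frame with per-epoch `epoch`,
#'   `train_loss`, `train_acc`, `test_loss`, `test_acc`).
#' @export
train_gnn <- function(graph, config, tc = train_config()) {
  stopifnot(inherits(graph, "graph_dataset"), inherits(config, "gnn_config"),
            inherits(tc, "train_config"))
  if (!any(graph$train_mask)) stop("training mask is empty")
  if (config$num_classes != nlevels(graph$labels)) {
    stop("configuration error: model has ", config$num_classes,
         " classes but the graph has ", nlevels(graph$labels))
  }
  graph <- cache_directed(graph)
  state <- gnn_init(ncol(graph$features), config, seed = tc$seed)
  state$classes <- levels(graph$labels)
  y_int <- as.integer(graph$labels)
  n <- nrow(graph$features)
  train_idx <- which(graph$train_mask)
  opt <- optimizer_init(state$params, tc)
  history <- vector("list", tc$epochs)

  for (epoch in seq_len(tc$epochs)) {
    set.seed(derive_seed(tc$seed, 100000L + epoch))
    order_idx <- sample(train_idx)
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / tc$batch_size))
    for (batch in batches) {
      fwd <- gnn_forward_full(graph, state, mode = "train")
      state$running <- fwd$running
      sel <- rep(FALSE, n)
      sel[batch] <- TRUE
      loss <- masked_ce(fwd$probs, y_int, sel)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      glogits <- fwd$probs
      glogits[cbind(batch, y_int[batch])] <-
        glogits[cbind(batch, y_int[batch])] - 1
      glogits[!sel, ] <- 0
      glogits <- glogits / length(batch)
      grads <- gnn_backward_full(glogits, fwd, state)
      step <- optimizer_step(opt, state$params, grads)
      state$params <- step$params
      opt <- step$opt
      if (!all(vapply(state$params,
                      function(p) all(is.finite(p)), logical(1)))) {
        stop("training diverged (non-finite parameters) at epoch ", epoch)
      }
    }
    # One dropout-free pass re-estimates the normalization moments on the
    # evaluation-time activation distribution (drop-induced variance
    # shift correction); its probabilities are the epoch's eval metrics.
    recal <- gnn_forward_full(graph, state, mode = "recalibrate")
    state$running <- recal$running
    probs <- recal$probs
    history[[epoch]] <- data.frame(
      epoch = epoch,
      train_loss = masked_ce(probs, y_int, graph$train_mask),
      train_acc = masked_acc(probs, y_int, graph$train_mask),
      test_loss = if (any(graph$test_mask)) {
        masked_ce(probs, y_int, graph$test_mask)
      } else NA_real_,
      test_acc = if (any(graph$test_mask)) {
        masked_acc(probs, y_int, graph$test_mask)
      } else NA_real_)
  }
  history <- if (tc$epochs > 0) {
    do.call(rbind, history)
  } else {
    data.frame(epoch = integer(0), train_loss = numeric(0),
               train_acc = numeric(0), test_loss = numeric(0),
               test_acc = numeric(0))
  }
  list(state = state, history = history)
}

#' Predict node labels
#'
#' Evaluation-mode forward pass followed by a per-node argmax; exact
#' probability ties resolve to the lower class index.
#'
#' @param object a trained `gnn_state`.
#' @param graph a `graph_dataset`.
#' @param ... unused.
#' @return factor of predicted labels, one per node.
#' @export
predict.gnn_state <- function(object, graph, ...) {
  probs <- gnn_forward(graph, object)
  pred <- apply(probs, 1, which.max)  # which.max takes the first maximum
  factor(levels(graph$labels)[pred], levels = levels(graph$labels))
}

#' @export
print.gnn_state <- function(x, ...) {
  cfg <- x$config
  cat("Message-passing classifier:", cfg$num_conv_layers,
      "conv layer(s), hidden [", paste(cfg$hidden_units, collapse = ", "),
      "],", cfg$aggregation, "aggregation,", cfg$combination,
      "combination,", cfg$activation, "activation\n")
  cat("Parameters:",
      sum(vapply(x$params, length, integer(1))), "values\n")
  invisible(x)
}
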
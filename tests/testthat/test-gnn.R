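ns <- asNamespace("anesgraph")

zero_block_state <- function(width, units) {
  list(gamma = rep(1, width), beta = rep(0, width),
       W = matrix(0, width, units), b = rep(0, units),
       mean = rep(0, width), var = rep(1, width))
}

test_that("ffn_block applies normalize -> dropout -> dense -> activation", {
  cfg <- ffn_block_config(units = 3, dropout_rate = 0, activation = "elu")
  st <- zero_block_state(6, 3)
  x <- matrix(0, 4, 6)
  expect_equal(ffn_block(x, st, cfg), matrix(0, 4, 3))  # elu(0) = 0

  # eval mode is deterministic even at positive dropout rate
  cfg2 <- ffn_block_config(units = 3, dropout_rate = 0.5)
  st2 <- zero_block_state(6, 3)
  set.seed(1)
  st2$W <- matrix(rnorm(18), 6, 3)
  xin <- matrix(rnorm(24), 4, 6)
  expect_identical(ffn_block(xin, st2, cfg2), ffn_block(xin, st2, cfg2))

  # hand-computed chain at frozen running moments
  st3 <- list(gamma = 2, beta = 0.5, W = matrix(1.5), b = -0.25,
              mean = 1, var = 4)
  cfg3 <- ffn_block_config(units = 1, dropout_rate = 0,
                           activation = "elu")
  x3 <- matrix(c(3, -1), 2, 1)
  xhat <- (x3 - 1) / sqrt(4 + 1e-5)
  z <- (2 * xhat + 0.5) * 1.5 - 0.25
  want <- ifelse(z > 0, z, exp(z) - 1)
  expect_equal(ffn_block(x3, st3, cfg3), want, tolerance = 1e-9)

  expect_error(ffn_block(matrix(0, 2, 4), st, cfg), "width")
})

test_that("stacked_ffn chains blocks with additive skips", {
  cfg <- ffn_block_config(units = 4, dropout_rate = 0)
  states <- replicate(4, zero_block_state(4, 4), simplify = FALSE)
  x <- matrix(rnorm(20), 5, 4)
  # all-zero dense weights: every block outputs 0 and the skips carry 0
  expect_equal(stacked_ffn(x, states, replicate(4, cfg, simplify = FALSE)),
               matrix(0, 5, 4))

  # identity second block doubles the accumulated signal: acc + block(acc)
  id_state <- zero_block_state(1, 1)
  id_state$W <- matrix(1)  # with BN at identity moments, block(x) ~ x
  first <- zero_block_state(1, 1)
  first$W <- matrix(1)
  x1 <- matrix(abs(rnorm(3)) + 0.5)  # positive, elu is identity there
  out <- stacked_ffn(x1, list(first, id_state),
                     list(ffn_block_config(1, 0), ffn_block_config(1, 0)))
  acc1 <- ffn_block(x1, first, ffn_block_config(1, 0))
  expect_equal(out, acc1 + ffn_block(acc1, id_state,
                                     ffn_block_config(1, 0)),
               tolerance = 1e-9)
})

test_that("aggregate_neighbors matches dense adjacency arithmetic", {
  # path graph 1-2-3
  e <- anesgraph:::edge_list(c(1, 2), c(2, 3), c(1, 1), "spearman")
  S <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  got <- aggregate_neighbors(S, e, "sum")
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(got, A %*% S)

  # mean over identical neighbor states returns that state
  S2 <- matrix(rep(c(5, -2), each = 3), 3, 2)
  expect_equal(aggregate_neighbors(S2, e, "mean"), A %*% S2 / pmax(rowSums(A), 1))

  # edgeless graph aggregates to zero
  e0 <- anesgraph:::edge_list(integer(0), integer(0), numeric(0), "spearman")
  expect_equal(aggregate_neighbors(S, e0, "max"), matrix(0, 3, 2))

  # max picks the elementwise maximum over neighbors
  got_max <- aggregate_neighbors(S, e, "max")
  expect_equal(got_max[2, ], pmax(S[1, ], S[3, ]))
  expect_equal(got_max[1, ], S[2, ])

  # edge weights scale the neighbor states when enabled
  ew <- anesgraph:::edge_list(c(1, 2), c(2, 3), c(0.5, 2), "spearman")
  got_w <- aggregate_neighbors(S, ew, "sum", use_edge_weights = TRUE)
  W <- matrix(c(0, 0.5, 0, 0.5, 0, 2, 0, 2, 0), 3, 3)
  expect_equal(got_w, W %*% S)
})

test_that("conv_layer reproduces the dense formulation on small graphs", {
  set.seed(21)
  for (trial in 1:10) {
    n <- sample(2:6, 1)
    h <- sample(1:3, 1)
    hp <- sample(1:3, 1)
    # random undirected graph on n nodes
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < 0.7
    if (!any(keep)) keep[1] <- TRUE
    e <- anesgraph:::edge_list(pairs[keep, 1], pairs[keep, 2],
                               runif(sum(keep)), "spearman")
    A <- matrix(0, n, n)
    A[cbind(e$target, e$source)] <- 1
    A <- A + t(A)
    F0 <- matrix(rnorm(n * h), n, h)
    W_self <- matrix(rnorm(h * hp), h, hp)
    W_neigh <- matrix(rnorm(h * hp), h, hp)
    cfg <- gnn_config(num_classes = 2, hidden_units = c(hp, hp),
                      aggregation = "sum", combination = "concat",
                      activation = "elu")
    layer <- list(W = rbind(W_self, W_neigh), b = rep(0, hp))
    got <- conv_layer(F0, e, layer, cfg)
    z <- A %*% F0 %*% W_neigh + F0 %*% W_self
    want <- ifelse(z > 0, z, exp(z) - 1)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("forward pass yields a probability simplex and equivariance", {
  g <- make_small_graph(n = 12, seed = 5)
  cfg <- gnn_config(num_classes = 2, hidden_units = c(5L, 5L))
  state <- ns$gnn_init(6, cfg, seed = 9)
  probs <- gnn_forward(g, state)
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 12), tolerance = 1e-9)

  # permuting nodes permutes the output rows
  perm <- sample(12)
  inv <- order(perm)
  g2 <- g
  g2$features <- g$features[perm, ]
  g2$labels <- g$labels[perm]
  tg <- inv[g$edges$target]
  sr <- inv[g$edges$source]
  swap <- tg > sr
  e2 <- anesgraph:::edge_list(ifelse(swap, sr, tg), ifelse(swap, tg, sr),
                              g$edges$weight, "spearman")
  g2$edges <- e2
  attr(g2, "directed") <- NULL
  probs2 <- gnn_forward(g2, state)
  expect_equal(probs2, probs[perm, ], tolerance = 1e-9)
})

test_that("an edgeless graph reduces to the per-node feed-forward path", {
  g <- make_small_graph(n = 8, seed = 3)
  g$edges <- anesgraph:::edge_list(integer(0), integer(0), numeric(0),
                                   "spearman")
  attr(g, "directed") <- NULL
  cfg <- gnn_config(num_classes = 2, hidden_units = c(4L, 4L))
  state <- ns$gnn_init(6, cfg, seed = 2)
  probs_all <- gnn_forward(g, state)
  # evaluation-mode BN uses stored moments, so nodes are independent:
  # feeding any single node alone gives the same row
  for (i in c(1, 5, 8)) {
    gi <- g
    gi$features <- g$features[i, , drop = FALSE]
    gi$labels <- g$labels[i]
    gi$train_mask <- TRUE
    gi$test_mask <- FALSE
    attr(gi, "directed") <- NULL
    expect_equal(gnn_forward(gi, state), probs_all[i, , drop = FALSE],
                 tolerance = 1e-9)
  }
})

test_that("analytic gradients match finite differences", {
  g <- ns$cache_directed(make_small_graph(n = 8, seed = 7))
  y <- as.integer(g$labels)
  for (setup in list(list(comb = "concat", agg = "sum"),
                     list(comb = "recurrent", agg = "max"))) {
    cfg <- gnn_config(num_classes = 2, hidden_units = c(4L, 3L),
                      aggregation = setup$agg, combination = setup$comb,
                      dropout_rate = 0)
    state <- ns$gnn_init(6, cfg, seed = 3)
    lossfun <- function(st) {
      fwd <- ns$gnn_forward_full(g, st, mode = "train")
      idx <- which(g$train_mask)
      -mean(log(fwd$probs[cbind(idx, y[idx])]))
    }
    fwd <- ns$gnn_forward_full(g, state, mode = "train")
    batch <- which(g$train_mask)
    glog <- fwd$probs
    glog[cbind(batch, y[batch])] <- glog[cbind(batch, y[batch])] - 1
    glog[setdiff(seq_len(8), batch), ] <- 0
    glog <- glog / length(batch)
    grads <- ns$gnn_backward_full(glog, fwd, state)
    eps <- 1e-6
    set.seed(4)
    for (nm in names(grads)) {
      p <- state$params[[nm]]
      for (i in sample(seq_along(p), min(length(p), 3))) {
        s2 <- state
        s2$params[[nm]][i] <- p[i] + eps
        lp <- lossfun(s2)
        s2$params[[nm]][i] <- p[i] - eps
        lm <- lossfun(s2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(unname(grads[[nm]][i]), num, tolerance = 1e-4,
                     label = paste(setup$comb, setup$agg, nm, i))
      }
    }
  }
})

test_that("training contracts: no-op epochs, determinism, learning", {
  g <- make_small_graph(n = 20, seed = 13)
  cfg <- gnn_config(num_classes = 2, hidden_units = c(8L, 8L))

  fit0 <- train_gnn(g, cfg, train_config(epochs = 0, seed = 5))
  expect_equal(nrow(fit0$history), 0)
  init <- ns$gnn_init(6, cfg, seed = 5)
  expect_equal(fit0$state$params, init$params)

  tc <- train_config(epochs = 8, seed = 5, batch_size = 8)
  fit1 <- train_gnn(g, cfg, tc)
  fit2 <- train_gnn(g, cfg, tc)
  expect_identical(fit1$state$params, fit2$state$params)
  expect_identical(fit1$history, fit2$history)

  # separable two-class toy: the loss must fall
  expect_lt(fit1$history$train_loss[8], fit1$history$train_loss[1])
  expect_true(all(vapply(fit1$state$params,
                         function(p) all(is.finite(p)), logical(1))))
})

test_that("every optimizer makes a finite, loss-reducing first epoch", {
  g <- make_small_graph(n = 16, seed = 17)
  cfg <- gnn_config(num_classes = 2, hidden_units = c(6L, 6L),
                    dropout_rate = 0)
  for (opt in c("sgd", "adam", "nadam", "adamax")) {
    fit <- train_gnn(g, cfg, train_config(optimizer = opt, epochs = 5,
                                          seed = 2, batch_size = 8))
    expect_true(all(is.finite(fit$history$train_loss)), label = opt)
    expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  }
})

test_that("prediction ties break toward the lower class index", {
  g <- make_small_graph(n = 6, seed = 1)
  cfg <- gnn_config(num_classes = 2, hidden_units = c(3L, 3L))
  state <- ns$gnn_init(6, cfg, seed = 1)
  state$classes <- levels(g$labels)
  # zero output weights force an exact 0.5/0.5 tie
  state$params[["out.W"]][] <- 0
  state$params[["out.b"]][] <- 0
  pred <- predict(state, g)
  expect_true(all(pred == levels(g$labels)[1]))

  # repeated evaluation is invariant
  expect_identical(predict(state, g), pred)
})

test_that("recurrent combination uses the gate activation", {
  g <- make_small_graph(n = 8, seed = 23)
  for (ract in c("softplus", "sigmoid", "tanh")) {
    cfg <- gnn_config(num_classes = 2, hidden_units = c(4L, 4L),
                      combination = "recurrent",
                      recurrent_activation = ract)
    state <- ns$gnn_init(6, cfg, seed = 11)
    probs <- gnn_forward(g, state)
    expect_equal(rowSums(probs), rep(1, 8), tolerance = 1e-9)
  }
})
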
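# Building blocks of the classifier: activations, the FFN block
# (batch normalization -> dropout -> dense + nonlinearity) and the
# residual stack of FFN blocks. Everything is plain matrix algebra with
# hand-derived gradients; shapes are (batch x width) throughout.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

act_forward <- function(name, z) {
  switch(name,
    elu = ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
    relu = pmax(z, 0),
    tanh = tanh(z),
    softmax = row_softmax(z),
    softplus = ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
    sigmoid = 1 / (1 + exp(-z)),
    stop("unknown activation: ", name))
}

# g is the upstream gradient; z the pre-activation, y = act(z).
act_backward <- function(name, g, z, y) {
  switch(name,
    elu = g * ifelse(z > 0, 1, y + 1),
    relu = g * (z > 0),
    tanh = g * (1 - y^2),
    softmax = (g - rowSums(g * y)) * y,
    softplus = g / (1 + exp(-z)),
    sigmoid = g * y * (1 - y),
    stop("unknown activation: ", name))
}

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Configure one FFN block
#'
#' An FFN block is the network's feed-forward unit: batch normalization of
#' its input, dropout, then a dense layer with a nonlinearity.
#'
#' @param units output width of the dense layer (>= 1).
#' @param dropout_rate fraction of units dropped during training, in
#'   `[0, 1)`; default 0.3.
#' @param activation `"elu"` (default), `"relu"`, `"tanh"` or `"softmax"`.
#' @return an `ffn_block_config` object.
#' @export
ffn_block_config <- function(units, dropout_rate = 0.3,
                             activation = "elu") {
  stopifnot(units >= 1, dropout_rate >= 0, dropout_rate < 1,
            activation %in% c("elu", "relu", "tanh", "softmax"))
  structure(list(units = as.integer(units), dropout_rate = dropout_rate,
                 activation = activation),
            class = "ffn_block_config")
}

# Initialize one block's parameters. Dense weights use symmetric uniform
# fan-in scaling; normalization starts at the identity (gamma 1, beta 0)
# with standard-normal running moments.
ffn_block_init <- function(input_dim, config) {
  limit <- sqrt(6 / input_dim)
  list(gamma = rep(1, input_dim),
       beta = rep(0, input_dim),
       W = matrix(runif(input_dim * config$units, -limit, limit),
                  input_dim, config$units),
       b = rep(0, config$units),
       mean = rep(0, input_dim),
       var = rep(1, input_dim))
}

# mode: "train" (batch statistics blended into the running moments,
# dropout active), "eval" (running moments, no dropout, deterministic) or
# "recalibrate" (batch statistics REPLACE the running moments, no
# dropout). Recalibration corrects the variance shift that dropout
# imprints on moments recorded during training: one dropout-free pass
# re-estimates every layer's moments on its actual evaluation-time input
# distribution.
ffn_block_core <- function(x, pars, config, mode = "eval") {
  training <- identical(mode, "train")
  x <- as.matrix(x)
  if (ncol(x) != length(pars$gamma)) {
    stop("ffn block input width ", ncol(x), " does not match block width ",
         length(pars$gamma))
  }
  m <- nrow(x)
  if (mode %in% c("train", "recalibrate") && m > 1) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v <- pmax(v, 0)
    if (mode == "train") {
      new_mean <- BN_MOMENTUM * pars$mean + (1 - BN_MOMENTUM) * mu
      new_var <- BN_MOMENTUM * pars$var + (1 - BN_MOMENTUM) * v
    } else {
      new_mean <- mu
      new_var <- v
    }
  } else {
    mu <- pars$mean
    v <- pars$var
    new_mean <- pars$mean
    new_var <- pars$var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(x, 2, mu), 2, invstd, "*")
  y1 <- sweep(sweep(xhat, 2, pars$gamma, "*"), 2, pars$beta, "+")
  if (training && config$dropout_rate > 0) {
    mask <- matrix((runif(length(y1)) >= config$dropout_rate) /
                     (1 - config$dropout_rate), nrow(y1), ncol(y1))
    y2 <- y1 * mask
  } else {
    mask <- NULL
    y2 <- y1
  }
  z <- y2 %*% pars$W
  z <- sweep(z, 2, pars$b, "+")
  out <- act_forward(config$activation, z)
  list(out = out,
       cache = list(x = x, xhat = xhat, invstd = invstd, mask = mask,
                    y2 = y2, z = z, out = out, training = training,
                    batch_norm = training && m > 1),
       running = list(mean = new_mean, var = new_var))
}

ffn_block_backward <- function(g, cache, pars, config) {
  gz <- act_backward(config$activation, g, cache$z, cache$out)
  gW <- crossprod(cache$y2, gz)
  gb <- colSums(gz)
  gy2 <- tcrossprod(gz, pars$W)
  gy1 <- if (is.null(cache$mask)) gy2 else gy2 * cache$mask
  ggamma <- colSums(gy1 * cache$xhat)
  gbeta <- colSums(gy1)
  gxhat <- sweep(gy1, 2, pars$gamma, "*")
  if (cache$batch_norm) {
    m <- nrow(cache$x)
    s1 <- colSums(gxhat)
    s2 <- colSums(gxhat * cache$xhat)
    gx <- sweep(m * gxhat - matrix(s1, m, length(s1), byrow = TRUE) -
                  sweep(cache$xhat, 2, s2, "*"),
                2, cache$invstd / m, "*")
  } else {
    gx <- sweep(gxhat, 2, cache$invstd, "*")
  }
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta, W = gW, b = gb))
}

#' Apply one FFN block
#'
#' Runs normalization, dropout and the dense nonlinearity on a batch of
#' row vectors. In evaluation mode dropout is the identity and
#' normalization uses the stored running moments, so the map is
#' deterministic.
#'
#' @param x numeric matrix (batch x input width).
#' @param block_state list with elements `gamma`, `beta`, `W`, `b`,
#'   `mean`, `var` (see `ffn_block_init`).
#' @param config an [ffn_block_config].
#' @param training logical; training mode draws dropout masks and uses
#'   batch statistics.
#' @return numeric matrix (batch x `config$units`).
#' @export
ffn_block <- function(x, block_state, config, training = FALSE) {
  ffn_block_core(x, block_state, config,
                 if (training) "train" else "eval")$out
}

# Residual chain over k blocks: acc = block1(x); acc = acc + block_i(acc)
# for i >= 2 (three skip connections for four blocks). When a block's
# output width differs from the accumulated width, a linear projection P
# carries the accumulated signal across the addition.
stacked_ffn_core <- function(x, states, configs, mode = "eval",
                             skip = TRUE) {
  stopifnot(length(states) == length(configs))
  caches <- vector("list", length(configs))
  step <- ffn_block_core(x, states[[1]], configs[[1]], mode)
  acc <- step$out
  caches[[1]] <- step
  for (i in seq_along(configs)[-1]) {
    step <- ffn_block_core(acc, states[[i]], configs[[i]], mode)
    if (skip) {
      carried <- if (is.null(states[[i]]$P)) {
        if (ncol(acc) != ncol(step$out)) {
          stop("skip connection width mismatch (", ncol(acc), " vs ",
               ncol(step$out), ") and no projection present")
        }
        acc
      } else {
        acc %*% states[[i]]$P
      }
      step$carried_in <- acc
      acc <- step$out + carried
    } else {
      acc <- step$out
    }
    caches[[i]] <- step
  }
  list(out = acc, caches = caches)
}

#' Apply a stack of FFN blocks with skip connections
#'
#' Blocks after the first are bridged by additive skip connections: the
#' accumulated output of the preceding blocks is added to each block's
#' output, so four blocks carry three skips. Blocks of differing widths
#' are joined through a learnable linear projection stored as `P` in the
#' downstream block's state.
#'
#' @param x numeric matrix (batch x input width).
#' @param states list of block states (see [ffn_block()]).
#' @param configs list of [ffn_block_config] objects, same length.
#' @param training logical.
#' @return numeric matrix (batch x last block's units).
#' @export
stacked_ffn <- function(x, states, configs, training = FALSE) {
  stacked_ffn_core(x, states, configs,
                   if (training) "train" else "eval", skip = TRUE)$out
}
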
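# Standard first-order update rules over the flat parameter list. Moment
# constants are the usual defaults (beta1 0.9, beta2 0.999, eps 1e-8);
# only the learning rate is exposed for tuning.

ADAM_B1 <- 0.9
ADAM_B2 <- 0.999
ADAM_EPS <- 1e-8

optimizer_init <- function(params, tc) {
  zeros <- lapply(params, function(p) p * 0)
  list(name = tc$optimizer, lr = tc$learning_rate, t = 0L,
       m = zeros, v = zeros)
}

optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  lr <- opt$lr
  t <- opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    switch(opt$name,
      sgd = {
        params[[nm]] <- params[[nm]] - lr * g
      },
      adam = {
        opt$m[[nm]] <- ADAM_B1 * opt$m[[nm]] + (1 - ADAM_B1) * g
        opt$v[[nm]] <- ADAM_B2 * opt$v[[nm]] + (1 - ADAM_B2) * g^2
        mhat <- opt$m[[nm]] / (1 - ADAM_B1^t)
        vhat <- opt$v[[nm]] / (1 - ADAM_B2^t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + ADAM_EPS)
      },
      nadam = {
        opt$m[[nm]] <- ADAM_B1 * opt$m[[nm]] + (1 - ADAM_B1) * g
        opt$v[[nm]] <- ADAM_B2 * opt$v[[nm]] + (1 - ADAM_B2) * g^2
        mhat <- opt$m[[nm]] / (1 - ADAM_B1^t)
        vhat <- opt$v[[nm]] / (1 - ADAM_B2^t)
        update <- ADAM_B1 * mhat + (1 - ADAM_B1) * g / (1 - ADAM_B1^t)
        params[[nm]] <- params[[nm]] - lr * update / (sqrt(vhat) + ADAM_EPS)
      },
      adamax = {
        opt$m[[nm]] <- ADAM_B1 * opt$m[[nm]] + (1 - ADAM_B1) * g
        opt$v[[nm]] <- pmax(ADAM_B2 * opt$v[[nm]], abs(g))
        params[[nm]] <- params[[nm]] -
          (lr / (1 - ADAM_B1^t)) * opt$m[[nm]] / (opt$v[[nm]] + ADAM_EPS)
      },
      stop("unknown optimizer: ", opt$name))
  }
  list(params = params, opt = opt)
}
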
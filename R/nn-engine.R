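# R side of the neural-network engine. The per-batch forward/backward
# kernels live in src/cnn.cpp; here sit the seeded parameter
# initialization, the Adam optimizer state, and the layout helpers.
#
# A minibatch of n encoded sequences is held channels-in-rows: a
# C x (n*L) matrix whose column c = (p-1)*n + i is position p of
# sequence i.

# He-style seeded initialization; caller controls the RNG stream
.initParams <- function(config) {
  F <- config@filters
  K <- config@kernelSize
  theta <- list()
  bnStats <- list()
  cin <- config@inputChannels
  for (b in seq_len(config@convBlocks)) {
    theta[[sprintf("c%d.W", b)]] <-
      matrix(rnorm(K * cin * F, sd = sqrt(2 / (K * cin))), F, K * cin)
    theta[[sprintf("c%d.b", b)]] <- numeric(F)
    theta[[sprintf("c%d.g", b)]] <- rep(1, F)
    theta[[sprintf("c%d.be", b)]] <- numeric(F)
    bnStats[[sprintf("c%d.mean", b)]] <- numeric(F)
    bnStats[[sprintf("c%d.var", b)]] <- rep(1, F)
    cin <- F
  }
  D <- flattenedDim(config)
  H <- config@fcSizes[2]
  theta[["fc1.W"]] <- matrix(rnorm(D * H, sd = sqrt(2 / D)), H, D)
  theta[["fc1.b"]] <- numeric(H)
  theta[["fc2.W"]] <- matrix(rnorm(H, sd = sqrt(1 / H)), 1, H)
  theta[["fc2.b"]] <- 0
  list(theta = theta, bnStats = bnStats)
}

.poolFlags <- function(config) {
  seq_len(config@convBlocks) %in% config@poolAfter
}

# one training step (forward, loss, backward) on a flattened batch
.trainStep <- function(theta, bnStats, config, X, y, n) {
  .cnnTrainStep(theta, bnStats, X, as.numeric(y), as.integer(n),
                config@inputLength, config@kernelSize, config@convBlocks,
                config@poolSize, .poolFlags(config))
}

.inferLogits <- function(theta, bnStats, config, X, n) {
  as.numeric(.cnnLogits(theta, bnStats, X, as.integer(n),
                        config@inputLength, config@kernelSize,
                        config@convBlocks, config@poolSize,
                        .poolFlags(config)))
}

# numerically stable binary cross entropy from logits
.bceLoss <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

.adamInit <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0),
       t = 0L)
}

.adamStep <- function(theta, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(theta = theta, state = state)
}

# flatten an n x L x C array into the engine's C x (n*L) layout
.flattenBatch <- function(x) {
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[1]
  out <- aperm(x, c(3, 1, 2))
  dim(out) <- c(dim(x)[3], dim(x)[1] * dim(x)[2])
  list(X = out, n = n)
}
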
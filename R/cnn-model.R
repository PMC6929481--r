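#' Create a CNN member configuration
#'
#' Defaults follow the reference architecture for 200 bp inputs: six
#' convolution blocks of 64 filters (kernel 3, `same` padding, batch
#' normalization, ReLU), max pooling of size 4 after blocks 3 and 6 —
#' leaving floor(floor(200/4)/4) = 12 positions x 64 filters = 768
#' flattened features — then fully connected 768 -> 256 (ReLU) -> 1
#' (sigmoid). Training defaults: 20 epochs, Adam with learning rate 1e-4,
#' binary cross entropy, batch size 32.
#'
#' @param inputLength Sequence length in bases.
#' @param inputChannels Channels per position (8 for the one-hot + k-mer
#'   encoding).
#' @param convBlocks Number of convolution blocks.
#' @param filters Filters per block.
#' @param kernelSize Convolution kernel width (odd).
#' @param poolSize Max-pooling window/stride.
#' @param poolAfter Block indices followed by a pooling layer.
#' @param fcSizes Sizes of the two fully connected layers; the first must
#'   equal [flattenedDim()] of the convolutional stack (computed
#'   automatically when `NULL`).
#' @param epochs Training epochs.
#' @param learningRate Adam learning rate.
#' @param batchSize Minibatch size.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A validated [CNNConfig-class].
#' @examples
#' flattenedDim(cnnConfig())  # 768
#' @export
cnnConfig <- function(inputLength = 200L, inputChannels = 8L,
                      convBlocks = 6L, filters = 64L, kernelSize = 3L,
                      poolSize = 4L, poolAfter = c(3L, 6L),
                      fcSizes = NULL, epochs = 20L, learningRate = 1e-4,
                      batchSize = 32L, seed = 1L) {
  if (is.null(fcSizes))
    fcSizes <- c(.flatDim(as.integer(inputLength), as.integer(convBlocks),
                          as.integer(poolAfter), as.integer(poolSize),
                          as.integer(filters)), 256L)
  new("CNNConfig",
    inputLength = as.integer(inputLength),
    inputChannels = as.integer(inputChannels),
    convBlocks = as.integer(convBlocks), filters = as.integer(filters),
    kernelSize = as.integer(kernelSize), poolSize = as.integer(poolSize),
    poolAfter = as.integer(poolAfter), fcSizes = as.integer(fcSizes),
    epochs = as.integer(epochs), learningRate = learningRate,
    batchSize = as.integer(batchSize), seed = as.integer(seed))
}

.flatDim <- function(inputLength, convBlocks, poolAfter, poolSize, filters) {
  len <- inputLength
  for (b in seq_len(convBlocks)) {
    if (b %in% poolAfter) {
      len <- len %/% poolSize
      if (len < 1L) stop("pooling reduces the sequence length to zero")
    }
  }
  as.integer(len * filters)
}

#' Flattened feature dimension of the convolutional stack
#'
#' Number of features entering the first fully connected layer: the
#' sequence length after all pooling layers (each pooling divides the
#' current length by `poolSize`, flooring) times the filter count. For
#' the default configuration this is `floor(floor(200/4)/4) * 64 = 768`.
#'
#' @param config A [CNNConfig-class].
#' @return Integer feature count.
#' @export
flattenedDim <- function(config) {
  .flatDim(config@inputLength, config@convBlocks, config@poolAfter,
           config@poolSize, config@filters)
}

#' Build an untrained CNN member
#'
#' Instantiates the network of [cnnConfig()] with seeded random weights
#' (He initialization for the convolution and ReLU layers). Two builds
#' with the same configuration (including seed) have identical parameters.
#'
#' @param config A [CNNConfig-class].
#' @return An untrained [CNNModel-class] (`chosenEpoch` is `NA`).
#' @export
buildModel <- function(config) {
  validObject(config)
  init <- withSeed(config@seed, .initParams(config))
  new("CNNModel", theta = init$theta, bnStats = init$bnStats,
      config = config, chosenEpoch = NA_integer_,
      valLoss = numeric(), trainLoss = numeric())
}

.checkInput <- function(x, config) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  if (length(dim(x)) != 3)
    stop("encoded input must be an n x L x C array or an L x C matrix")
  if (dim(x)[2] != config@inputLength || dim(x)[3] != config@inputChannels)
    stop(sprintf("input shape %d x %d does not match the configured %d x %d",
                 dim(x)[2], dim(x)[3], config@inputLength,
                 config@inputChannels))
  x
}

.asEncoded <- function(x, config) {
  if (is(x, "EnhancerSet") || is(x, "DNAStringSet") ||
      (is.character(x) && is.null(dim(x))))
    x <- encodeDataset(x)
  .checkInput(x, config)
}

#' Train a CNN member
#'
#' Runs exactly `config@epochs` epochs of minibatch Adam on the binary
#' cross entropy loss, recording the validation loss after every epoch
#' (computed in inference mode with frozen batch-norm statistics) and
#' keeping the weights of the epoch with minimal validation loss (first
#' minimum on ties). Batches are reshuffled every epoch from the
#' configuration seed, so a rerun with identical inputs reproduces the
#' same model.
#'
#' @param xTrain,xVal Encoded inputs (`n x L x 8` arrays from
#'   [encodeDataset()]).
#' @param yTrain,yVal Binary 0/1 label vectors.
#' @param config A [CNNConfig-class].
#' @return A trained [CNNModel-class].
#' @export
trainModel <- function(xTrain, yTrain, xVal, yVal, config = cnnConfig()) {
  xTrain <- .checkInput(xTrain, config)
  xVal <- .checkInput(xVal, config)
  n <- dim(xTrain)[1]
  if (n == 0 || length(yTrain) != n)
    stop("training set empty or labels mismatched")
  if (dim(xVal)[1] == 0 || length(yVal) != dim(xVal)[1])
    stop("validation set empty or labels mismatched")
  if (length(unique(yTrain)) < 2)
    stop("training set must contain both classes")
  idsT <- dimnames(xTrain)[[1]]; idsV <- dimnames(xVal)[[1]]
  if (!is.null(idsT) && !is.null(idsV) && length(intersect(idsT, idsV)))
    stop("training and validation sets share record ids")

  yTrain <- as.numeric(yTrain)
  bs <- min(config@batchSize, n)
  model <- withSeed(config@seed, {
    init <- .initParams(config)
    theta <- init$theta
    bnStats <- init$bnStats
    adam <- .adamInit(theta)
    best <- NULL
    valLoss <- trainLoss <- numeric(config@epochs)
    for (epoch in seq_len(config@epochs)) {
      perm <- sample(n)
      starts <- seq(1, n, by = bs)
      eLoss <- numeric(length(starts))
      for (s in seq_along(starts)) {
        take <- perm[starts[s]:min(starts[s] + bs - 1, n)]
        fb <- .flattenBatch(xTrain[take, , , drop = FALSE])
        step <- .trainStep(theta, bnStats, config, fb$X, yTrain[take], fb$n)
        bnStats <- step$bnStats
        eLoss[s] <- step$loss
        upd <- .adamStep(theta, step$grads, adam, config@learningRate)
        theta <- upd$theta
        adam <- upd$state
      }
      trainLoss[epoch] <- mean(eLoss)
      valLoss[epoch] <- .bceLoss(
        .predictLogits(theta, bnStats, config, xVal), as.numeric(yVal))
      if (is.null(best) || valLoss[epoch] < best$loss)
        best <- list(loss = valLoss[epoch], theta = theta,
                     bnStats = bnStats, epoch = epoch)
    }
    new("CNNModel", theta = best$theta, bnStats = best$bnStats,
        config = config, chosenEpoch = as.integer(best$epoch),
        valLoss = valLoss, trainLoss = trainLoss)
  })
  model
}

# inference-mode logits, batched to bound memory
.predictLogits <- function(theta, bnStats, config, x, batch = 256L) {
  n <- dim(x)[1]
  if (!n) return(numeric())
  out <- numeric(n)
  for (s in seq(1, n, by = batch)) {
    take <- s:min(s + batch - 1, n)
    fb <- .flattenBatch(x[take, , , drop = FALSE])
    out[take] <- .inferLogits(theta, bnStats, config, fb$X, fb$n)
  }
  out
}

#' @describeIn predictProba Probabilities from a single member.
#' @export
setMethod("predictProba", "CNNModel", function(model, x) {
  x <- .asEncoded(x, model@config)
  p <- stats::plogis(.predictLogits(model@theta, model@bnStats,
                                    model@config, x))
  names(p) <- dimnames(x)[[1]]
  p
})

setMethod("show", "CNNModel", function(object) {
  cfg <- object@config
  cat(sprintf("CNNModel: %d conv blocks (%d filters, kernel %d), input %d x %d\n",
              cfg@convBlocks, cfg@filters, cfg@kernelSize,
              cfg@inputLength, cfg@inputChannels))
  if (is.na(object@chosenEpoch)) {
    cat("  untrained\n")
  } else {
    cat(sprintf("  trained %d epochs; kept epoch %d (val loss %.4f)\n",
                length(object@valLoss), object@chosenEpoch,
                object@valLoss[object@chosenEpoch]))
  }
  invisible(object)
})

setMethod("show", "CNNConfig", function(object) {
  cat(sprintf(
    "CNNConfig: input %d x %d | %d conv blocks x %d filters (kernel %d) | pool %d after blocks %s\n",
    object@inputLength, object@inputChannels, object@convBlocks,
    object@filters, object@kernelSize, object@poolSize,
    paste(object@poolAfter, collapse = ",")))
  cat(sprintf(
    "  flatten %d -> fc %d -> 1 | %d epochs, lr %g, batch %d, seed %d\n",
    object@fcSizes[1], object@fcSizes[2], object@epochs,
    object@learningRate, object@batchSize, object@seed))
  invisible(object)
})
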
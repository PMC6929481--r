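#' @import methods
#' @importFrom stats median pt rnorm sd setNames
#' @importFrom utils head tail write.table read.table
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Labeled set of fixed-length DNA sequences
#'
#' `EnhancerSet` holds a collection of same-length DNA sequences over the
#' alphabet \{A, C, G, T\} together with an optional binary class label per
#' sequence (1 = positive, 0 = negative) and a task tag naming which of the
#' two prediction problems the labels refer to: `"identification"`
#' (enhancer vs non-enhancer) or `"classification"` (strong vs weak
#' enhancer).
#'
#' @slot sequences A [Biostrings::DNAStringSet] with unique names (record
#'   ids); all widths equal, alphabet restricted to A/C/G/T.
#' @slot label Integer vector parallel to `sequences`: 0, 1 or `NA` for
#'   unlabeled records.
#' @slot task Character scalar, `"identification"`, `"classification"` or
#'   `""` for untagged collections.
#'
#' @seealso [EnhancerSet()] for the user constructor, [loadBenchmark()],
#'   [simulateDataset()].
#' @exportClass EnhancerSet
setClass("EnhancerSet",
  representation(
    sequences = "DNAStringSet",
    label = "integer",
    task = "character"
  )
)

setValidity("EnhancerSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@label) != n)
    msg <- c(msg, "length(label) must equal the number of sequences")
  if (!all(object@label %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "labels must be 0, 1 or NA")
  if (n > 0) {
    if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
      msg <- c(msg, "sequences must carry unique names (record ids)")
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) > 1)
      msg <- c(msg, "all sequences must have the same length")
    if (any(w == 0))
      msg <- c(msg, "sequences must be non-empty")
    freq <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
    bad <- which(freq[, "other"] > 0)
    if (length(bad))
      msg <- c(msg, sprintf(
        "sequence '%s' contains characters outside {A,C,G,T}",
        names(object@sequences)[bad[1]]))
  }
  if (length(object@task) != 1 ||
      !object@task %in% c("identification", "classification", ""))
    msg <- c(msg, "task must be one of 'identification', 'classification' or ''")
  if (length(msg)) msg else TRUE
})

#' Stratified fold assignment of a labeled dataset
#'
#' Maps every record of an [EnhancerSet] to one of `k` folds such that,
#' within each class, fold sizes differ by at most one (exact
#' stratification). Produced by [stratifiedPartition()].
#'
#' @slot k Integer fold count.
#' @slot fold Integer vector in `1..k`, named by record id.
#' @slot seed Integer seed that drove the within-class shuffling.
#'
#' @exportClass FoldAssignment
setClass("FoldAssignment",
  representation(k = "integer", fold = "integer", seed = "integer")
)

setValidity("FoldAssignment", function(object) {
  msg <- character()
  if (length(object@k) != 1 || object@k < 2L)
    msg <- c(msg, "k must be a single integer >= 2")
  if (length(object@fold) > 0) {
    if (is.null(names(object@fold)))
      msg <- c(msg, "fold vector must be named by record id")
    if (any(object@fold < 1L | object@fold > object@k))
      msg <- c(msg, "fold indices must lie in 1..k")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of one convolutional network member
#'
#' Hyperparameters of a single 1-D CNN: six convolution blocks
#' (convolution with `same` padding, batch normalization, ReLU), max
#' pooling after the blocks listed in `poolAfter`, a flatten, and two
#' fully connected layers (`fcSizes[1]` -> `fcSizes[2]` with ReLU, then
#' `fcSizes[2]` -> 1 with sigmoid). `fcSizes[1]` must equal the flattened
#' dimension implied by `inputLength`, the pooling layout and
#' `filters` (see [flattenedDim()]); for the default 200 x 8 input this is
#' 64 filters x 12 positions = 768 features.
#'
#' @slot inputLength Sequence length in bases (default 200).
#' @slot inputChannels Encoding channels per position (8: 4 one-hot + x,y,z,t).
#' @slot convBlocks Number of convolution blocks (6).
#' @slot filters Filters per convolution block (64).
#' @slot kernelSize Convolution kernel width in positions (3).
#' @slot poolSize Max-pooling window and stride (4).
#' @slot poolAfter Blocks after which a pooling layer sits (3 and 6).
#' @slot fcSizes Sizes of the two fully connected layers (768, 256).
#' @slot epochs Training epochs (20).
#' @slot learningRate Adam learning rate (1e-4).
#' @slot batchSize Minibatch size (32).
#' @slot seed Integer seed for weight initialization and batch shuffling.
#'
#' @seealso [cnnConfig()], [flattenedDim()], [buildModel()].
#' @exportClass CNNConfig
setClass("CNNConfig",
  representation(
    inputLength = "integer", inputChannels = "integer",
    convBlocks = "integer", filters = "integer", kernelSize = "integer",
    poolSize = "integer", poolAfter = "integer", fcSizes = "integer",
    epochs = "integer", learningRate = "numeric", batchSize = "integer",
    seed = "integer"
  )
)

setValidity("CNNConfig", function(object) {
  msg <- character()
  if (object@inputLength < 3L) msg <- c(msg, "inputLength must be >= 3")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(object@fcSizes) != 2L)
    msg <- c(msg, "fcSizes must give the two fully connected layer sizes")
  if (any(object@poolAfter > object@convBlocks))
    msg <- c(msg, "poolAfter indices must not exceed convBlocks")
  fd <- tryCatch(flattenedDim(object), error = function(e) NA_integer_)
  if (is.na(fd))
    msg <- c(msg, "pooling reduces the sequence length to zero")
  else if (length(object@fcSizes) == 2L && fd != object@fcSizes[1])
    msg <- c(msg, sprintf(
      "flattened dimension (%d) does not match fcSizes[1] (%d)",
      fd, object@fcSizes[1]))
  if (length(msg)) msg else TRUE
})

#' A single CNN member (untrained or trained)
#'
#' Holds the network weights (`theta`), the batch-normalization running
#' statistics (`bnStats`), the configuration, and — once trained — the
#' per-epoch loss curves and the epoch whose weights were retained
#' (the first epoch minimizing validation loss).
#'
#' @slot theta Named list of weight arrays.
#' @slot bnStats Named list of batch-norm running means/variances.
#' @slot config A [CNNConfig-class].
#' @slot chosenEpoch Integer; `NA` until trained.
#' @slot valLoss Numeric per-epoch validation loss history.
#' @slot trainLoss Numeric per-epoch mean training loss history.
#'
#' @seealso [buildModel()], [trainModel()], [predictProba()].
#' @exportClass CNNModel
setClass("CNNModel",
  representation(
    theta = "list", bnStats = "list", config = "CNNConfig",
    chosenEpoch = "integer", valLoss = "numeric", trainLoss = "numeric"
  )
)

setValidity("CNNModel", function(object) {
  msg <- character()
  if (length(object@valLoss)) {
    ce <- object@chosenEpoch
    if (is.na(ce) || ce < 1L || ce > length(object@valLoss))
      msg <- c(msg, "chosenEpoch must index the validation loss history")
    else if (ce != which.min(object@valLoss))
      msg <- c(msg, "chosenEpoch must be the first minimum of the validation loss")
  }
  if (length(msg)) msg else TRUE
})

#' Ensemble of five cross-validation CNN members
#'
#' Five [CNNModel-class] members, each trained with one fold of a
#' stratified 5-fold split of the development set as its validation set,
#' plus the rule used to combine their five per-sequence hypotheses
#' H1..H5 into one probability H and a class call at threshold 0.5.
#'
#' @slot members List of 5 trained [CNNModel-class] objects.
#' @slot combiner `"averaging"` (default), `"voting"` or `"median"`.
#' @slot threshold Decision threshold (0.5; class 1 iff H >= threshold).
#' @slot task Task tag of the development data.
#' @slot seed Trial seed the fold split and member seeds derive from.
#'
#' @seealso [trainEnsemble()], [predict,CNNEnsemble-method].
#' @exportClass CNNEnsemble
setClass("CNNEnsemble",
  representation(
    members = "list", combiner = "character", threshold = "numeric",
    task = "character", seed = "integer"
  )
)

setValidity("CNNEnsemble", function(object) {
  msg <- character()
  if (length(object@members) != 5L)
    msg <- c(msg, "an ensemble has exactly 5 members")
  if (!all(vapply(object@members, is, logical(1), class2 = "CNNModel")))
    msg <- c(msg, "members must be CNNModel objects")
  if (!object@combiner %in% c("averaging", "voting", "median"))
    msg <- c(msg, "combiner must be 'averaging', 'voting' or 'median'")
  if (length(object@threshold) != 1 || object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0,1)")
  if (length(msg)) msg else TRUE
})
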
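.checkHypotheses <- function(h) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  if (ncol(h) != 5)
    stop("a hypothesis set holds exactly 5 member probabilities")
  if (any(h < 0 | h > 1)) stop("hypotheses must lie in [0, 1]")
  h
}

#' Combine five member hypotheses
#'
#' Given the five member probabilities H1..H5 for each sequence, the three
#' rules are:
#' \describe{
#'   \item{voting}{each Hi is first mapped to a class (1 iff
#'     `Hi >= threshold`); the majority class wins — five voters can never
#'     tie.}
#'   \item{averaging}{H = mean(H1..H5); class 1 iff `H >= threshold`. The
#'     default combiner of the framework.}
#'   \item{median}{H = median(H1..H5); class by the same threshold.}
#' }
#'
#' @param h Numeric vector of 5 probabilities, or an `n x 5` matrix (one
#'   row per sequence).
#' @param threshold Decision threshold, default 0.5.
#' @return `combineVoting`: integer class vector. `combineAveraging` and
#'   `combineMedian`: `data.frame(prob, class)`.
#' @examples
#' combineVoting(c(0.9, 0.8, 0.7, 0.1, 0.2))    # 1
#' combineAveraging(c(0.6, 0.6, 0.6, 0.4, 0.4)) # H = 0.52 -> class 1
#' combineMedian(c(0.3, 0.3, 0.3, 0.9, 0.9))    # H = 0.3 -> class 0
#' @name combiners
NULL

#' @rdname combiners
#' @export
combineVoting <- function(h, threshold = 0.5) {
  h <- .checkHypotheses(h)
  as.integer(rowSums(h >= threshold) >= 3)
}

#' @rdname combiners
#' @export
combineAveraging <- function(h, threshold = 0.5) {
  h <- .checkHypotheses(h)
  p <- rowMeans(h)
  data.frame(prob = p, class = as.integer(p >= threshold))
}

#' @rdname combiners
#' @export
combineMedian <- function(h, threshold = 0.5) {
  h <- .checkHypotheses(h)
  p <- apply(h, 1, median)
  data.frame(prob = p, class = as.integer(p >= threshold))
}

#' Train a five-member cross-validation ensemble
#'
#' Rotates the folds of a stratified 5-fold split: member m is trained on
#' folds != m and validated on fold m, so the five training subsets
#' jointly cover the whole development set. Member m's weights are
#' initialized from seed `seed * 100 + m`, derived from the trial seed.
#'
#' @param dev Fully labeled development [EnhancerSet-class].
#' @param folds A [FoldAssignment-class] with `k = 5` over `dev`
#'   (computed from `seed` when missing).
#' @param config A [CNNConfig-class]; its `seed` slot is overridden per
#'   member.
#' @param combiner `"averaging"` (default), `"voting"` or `"median"`.
#' @param seed Trial seed (drives the fold split and member seeds).
#' @param encoded Optional pre-computed `encodeDataset(dev)` array, to
#'   avoid re-encoding across trials.
#' @return A [CNNEnsemble-class].
#' @export
trainEnsemble <- function(dev, folds = NULL, config = cnnConfig(),
                          combiner = "averaging", seed = 3L,
                          encoded = NULL) {
  if (is.null(folds)) folds <- stratifiedPartition(dev, k = 5L, seed = seed)
  if (folds@k != 5L) stop("the ensemble uses a 5-fold split")
  fold <- foldIndices(folds)[names(dev)]
  if (anyNA(fold)) stop("fold assignment does not cover the dataset")
  if (is.null(encoded)) encoded <- encodeDataset(dev)
  y <- classLabels(dev)
  members <- vector("list", 5L)
  for (m in seq_len(5L)) {
    cfg <- config
    cfg@seed <- as.integer(seed * 100L + m)
    val <- fold == m
    members[[m]] <- tryCatch(
      trainModel(encoded[!val, , , drop = FALSE], y[!val],
                 encoded[val, , , drop = FALSE], y[val], cfg),
      error = function(e)
        stop(sprintf("training member %d (validation fold %d) failed: %s",
                     m, m, conditionMessage(e))))
  }
  new("CNNEnsemble", members = members, combiner = combiner,
      threshold = 0.5, task = taskType(dev), seed = as.integer(seed))
}

#' Ensemble prediction with full hypothesis provenance
#'
#' Queries the five members independently and applies the configured
#' combiner at threshold 0.5.
#'
#' @param object A [CNNEnsemble-class].
#' @param newdata An [EnhancerSet-class], [Biostrings::DNAStringSet],
#'   character vector of sequences, or pre-encoded `n x L x 8` array.
#' @return `data.frame` with columns `id`, `H1`..`H5` (member
#'   probabilities), `H` (combined probability; for voting, the vote
#'   fraction) and `class`.
#' @export
setMethod("predict", "CNNEnsemble", function(object, newdata) {
  enc <- .asEncoded(newdata, object@members[[1]]@config)
  n <- dim(enc)[1]
  ids <- dimnames(enc)[[1]]
  if (is.null(ids)) ids <- if (n) paste0("seq_", seq_len(n)) else character()
  H <- vapply(object@members, function(m) {
    p <- predictProba(m, enc)
    if (!n) numeric(0) else as.numeric(p)
  }, numeric(n))
  if (!n)
    return(data.frame(id = character(), H1 = numeric(), H2 = numeric(),
                      H3 = numeric(), H4 = numeric(), H5 = numeric(),
                      H = numeric(), class = integer()))
  H <- matrix(H, nrow = n)
  comb <- switch(object@combiner,
    averaging = combineAveraging(H, object@threshold),
    median = combineMedian(H, object@threshold),
    voting = {
      cls <- combineVoting(H, object@threshold)
      data.frame(prob = rowMeans(H >= object@threshold), class = cls)
    })
  out <- data.frame(id = ids, H, comb$prob, comb$class)
  names(out) <- c("id", paste0("H", 1:5), "H", "class")
  out
})

setMethod("show", "CNNEnsemble", function(object) {
  cat(sprintf("CNNEnsemble: 5 members, combiner '%s', threshold %.2f",
              object@combiner, object@threshold))
  if (nzchar(object@task)) cat(sprintf(", task: %s", object@task))
  cat(sprintf(" (trial seed %d)\n", object@seed))
  invisible(object)
})

#' Repeated independent-test trials
#'
#' Runs the full evaluation protocol: for each trial seed, re-partition
#' the development set into 5 stratified folds, train the five members by
#' fold rotation, build the averaging ensemble, and evaluate both every
#' member and the ensemble on the independent test set. Default seeds are
#' the ten odd integers 3, 5, ..., 21.
#'
#' @param dev,test Labeled development and independent-test
#'   [EnhancerSet-class] objects.
#' @param config A [CNNConfig-class].
#' @param seeds Integer vector of trial seeds (one trial each).
#' @param combiner Combiner rule for the ensembles.
#' @return List of per-trial results; each element has `trial`, `seed`,
#'   `member` (5-row metrics `data.frame`) and `ensemble` (1-row metrics
#'   `data.frame`). Failed trials are reported and returned as `NULL`
#'   elements.
#' @seealso [trialTable()] to lay the results out like the benchmark
#'   report tables, [summarizeTrials()].
#' @export
runTrials <- function(dev, test, config = cnnConfig(),
                      seeds = seq(3L, 21L, by = 2L),
                      combiner = "averaging") {
  encDev <- encodeDataset(dev)
  encTest <- encodeDataset(test)
  yTest <- classLabels(test)
  results <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    results[[i]] <- tryCatch({
      ens <- trainEnsemble(dev, config = config, combiner = combiner,
                           seed = seeds[i], encoded = encDev)
      pred <- predict(ens, encTest)
      member <- do.call(rbind, lapply(1:5, function(m)
        computeMetrics(yTest, pred[[paste0("H", m)]])))
      member <- cbind(model = paste0("Model ", 1:5), member)
      ensemble <- cbind(model = "Ensemble",
                        computeMetrics(yTest, pred$H))
      list(trial = i, seed = seeds[i], member = member, ensemble = ensemble)
    }, error = function(e) {
      warning(sprintf("trial %d (seed %d) failed: %s", i, seeds[i],
                      conditionMessage(e)))
      NULL
    })
  }
  results
}

#' Lay repeated-trial results out as a report table
#'
#' One row per trial (ensemble metrics), plus `Mean` and `SD` rows.
#'
#' @param results Output of [runTrials()].
#' @return `data.frame` with columns `trial`, `ACC`, `AUC`, `SN`, `SP`,
#'   `MCC`.
#' @export
trialTable <- function(results) {
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no successful trials")
  rows <- do.call(rbind, lapply(results, function(r)
    r$ensemble[, c("ACC", "AUC", "SN", "SP", "MCC")]))
  summ <- summarizeTrials(rows)
  out <- rbind(cbind(trial = as.character(seq_len(nrow(rows))), rows),
               cbind(trial = "Mean", summ["mean", , drop = FALSE]),
               cbind(trial = "SD", summ["sd", , drop = FALSE]))
  rownames(out) <- NULL
  out
}
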
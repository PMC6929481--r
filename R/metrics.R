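#' Confusion counts of a binary prediction
#'
#' @param labels Binary 0/1 truth vector.
#' @param predictions Binary 0/1 predicted classes, same length.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have the same length")
  if (!length(labels)) stop("empty input")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  c(TP = sum(labels == 1L & predictions == 1L),
    FP = sum(labels == 0L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FN = sum(labels == 1L & predictions == 0L))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TP+TN)/total`, `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`. A
#' sensitivity or specificity whose class is absent is returned as `NA`
#' (undefined), never coerced to a number.
#'
#' @param counts Named vector from [confusionCounts()].
#' @return Named numeric vector `c(ACC, SN, SP)`.
#' @export
basicMetrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  c(ACC = (tp + tn) / total,
    SN = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    SP = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' correlation between truth and prediction over all four confusion
#' cells, in `[-1, 1]`. When any marginal sum is zero the value is
#' undefined and returned as `NA` (flagged, distinct from 0).
#'
#' @param counts Named vector from [confusionCounts()].
#' @return Numeric scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
mccScore <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) estimator: the probability that a random positive
#' is scored above a random negative, with ties counted 1/2. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param labels Binary 0/1 truth vector; both classes must be present.
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have the same length")
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0 || nNeg == 0)
    stop("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' All five evaluation metrics of a scored test set
#'
#' Thresholds the scores (class 1 iff `score >= threshold`) and reports
#' ACC, AUC, SN, SP and MCC as a one-row `data.frame`.
#'
#' @param labels Binary 0/1 truth vector.
#' @param scores Probability scores in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5.
#' @return One-row `data.frame` with columns `ACC`, `AUC`, `SN`, `SP`,
#'   `MCC`.
#' @export
computeMetrics <- function(labels, scores, threshold = 0.5) {
  cc <- confusionCounts(labels, as.integer(scores >= threshold))
  bm <- basicMetrics(cc)
  data.frame(ACC = bm[["ACC"]], AUC = aucScore(labels, scores),
             SN = bm[["SN"]], SP = bm[["SP"]], MCC = mccScore(cc))
}

#' Mean and standard deviation across repeated trials
#'
#' Column-wise arithmetic mean and sample standard deviation (n - 1
#' denominator) of a collection of metric reports, e.g. the ensemble rows
#' of [runTrials()]. Values are rounded to 3 decimals for display, the
#' precision used in the benchmark report tables.
#'
#' @param reports `data.frame` (or coercible) with one row per trial and
#'   one column per metric.
#' @param digits Rounding for display; `NULL` to skip rounding.
#' @return `data.frame` with rows `mean` and `sd`.
#' @export
summarizeTrials <- function(reports, digits = 3) {
  reports <- as.data.frame(reports)
  if (!nrow(reports)) stop("no reports to summarize")
  num <- vapply(reports, is.numeric, logical(1))
  reports <- reports[, num, drop = FALSE]
  mu <- vapply(reports, mean, numeric(1))
  s <- if (nrow(reports) >= 2) vapply(reports, sd, numeric(1))
       else rep(NA_real_, ncol(reports))
  out <- rbind(mean = mu, sd = s)
  if (!is.null(digits)) out <- .roundHalfUp(out, digits)
  as.data.frame(out)
}

# round half away from zero, the display convention of the report tables
# (base round() is half-even: round(0.6775, 3) would print 0.677)
.roundHalfUp <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
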
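#' Per-position nucleotide frequencies of a sequence set
#'
#' `frequency(i, b)` is the fraction of sequences carrying nucleotide `b`
#' at position `i`; each position's four frequencies sum to 1.
#'
#' @param x An [EnhancerSet-class] (optionally restricted to one class
#'   via `class`), [Biostrings::DNAStringSet] or character vector.
#' @param class Optional 0/1: restrict to records with that label.
#' @return Numeric `L x 4` matrix, columns `A`, `C`, `G`, `T`.
#' @export
positionalFrequencies <- function(x, class = NULL) {
  if (is(x, "EnhancerSet")) {
    if (!is.null(class)) x <- x[which(classLabels(x) == class)]
    x <- sequences(x)
  }
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (!length(x)) stop("no sequences in the requested class")
  cm <- Biostrings::consensusMatrix(x, baseOnly = TRUE)
  t(cm[NUCLEOTIDES, , drop = FALSE]) / length(x)
}

#' Two-sample-logo-style positional enrichment test
#'
#' For every position and nucleotide, compares the per-sequence binary
#' occurrence indicator between a positive and a negative sequence set
#' with a two-sided pooled-variance independent t-test, and labels the
#' nucleotide `enriched` (significantly more frequent in the positive
#' set), `depleted` (significantly less frequent) or `not_significant`
#' at level `alpha`. No multiple-testing correction is applied; the
#' comparison is the raw per-cell p < alpha rule. When both groups are
#' constant at a position (zero pooled variance) the p-value is 0 if the
#' group means differ and 1 if they coincide, the limit of the statistic.
#'
#' @param pos,neg The two sequence sets ([EnhancerSet-class],
#'   [Biostrings::DNAStringSet] or character vectors), all sequences the
#'   same length, at least 2 per set.
#' @param alpha Significance level, default 0.05.
#' @return `data.frame` with one row per (position, nucleotide):
#'   `position`, `nucleotide`, `freqPos`, `freqNeg`, `pValue`, `status`.
#' @examples
#' pos <- simulateDataset(30, length = 40, gcPositive = 0.7,
#'                        gcNegative = 0.7, seed = 1)
#' neg <- simulateDataset(30, length = 40, gcPositive = 0.3,
#'                        gcNegative = 0.3, seed = 2)
#' logo <- twoSampleLogo(sequences(pos), sequences(neg))
#' table(logo$status)
#' @export
twoSampleLogo <- function(pos, neg, alpha = 0.05) {
  asSet <- function(x) {
    if (is(x, "EnhancerSet")) x <- sequences(x)
    if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
    x
  }
  pos <- asSet(pos); neg <- asSet(neg)
  n1 <- length(pos); n2 <- length(neg)
  if (n1 < 2 || n2 < 2)
    stop("each set needs at least 2 sequences (variance undefined otherwise)")
  L1 <- unique(Biostrings::width(pos)); L2 <- unique(Biostrings::width(neg))
  if (length(L1) != 1 || length(L2) != 1 || L1 != L2)
    stop("all sequences in both sets must share one length")
  L <- L1

  f1 <- positionalFrequencies(pos)   # L x 4 proportions
  f2 <- positionalFrequencies(neg)

  # pooled-variance t-test on 0/1 indicators, closed form per cell:
  # group variance of a binary indicator with mean p is n/(n-1) p(1-p)
  s1 <- f1 * (1 - f1) * n1 / (n1 - 1)
  s2 <- f2 * (1 - f2) * n2 / (n2 - 1)
  sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (f1 - f2) / se
  df <- n1 + n2 - 2
  pval <- 2 * pt(-abs(tstat), df)
  # zero pooled variance: both groups constant at this cell
  degen <- se == 0
  pval[degen & (f1 != f2)] <- 0
  pval[degen & (f1 == f2)] <- 1

  status <- ifelse(pval < alpha,
                   ifelse(f1 > f2, "enriched", "depleted"),
                   "not_significant")
  out <- data.frame(
    position = rep(seq_len(L), times = 4L),
    nucleotide = rep(NUCLEOTIDES, each = L),
    freqPos = as.vector(f1), freqNeg = as.vector(f2),
    pValue = as.vector(pval), status = as.vector(status))
  out[order(out$position, out$nucleotide), , drop = FALSE]
}

#' Write logo annotations as delimited text
#'
#' @param logo Output of [twoSampleLogo()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
writeLogoAnnotations <- function(logo, path) {
  write.table(logo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
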
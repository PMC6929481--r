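#' Simulate a GC-contrast labeled dataset
#'
#' Generates `nPerClass` positive and `nPerClass` negative sequences of
#' the given length. Every position is drawn i.i.d. with
#' `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`, using the class's
#' GC fraction — positives GC-rich and negatives AT-rich mirrors the
#' enrichment direction observed between real enhancers and
#' non-enhancers. The same seed always yields byte-identical output.
#'
#' @param nPerClass Sequences per class.
#' @param length Sequence length in bases (default 200, the benchmark
#'   fragment length).
#' @param gcPositive,gcNegative Target GC fractions of the two classes.
#' @param seed Integer seed.
#' @param task Task tag for the resulting [EnhancerSet-class].
#' @param idPrefix Prefixes for positive/negative record ids.
#' @return A labeled [EnhancerSet-class] (positives first).
#' @export
simulateDataset <- function(nPerClass, length = 200L, gcPositive = 0.6,
                            gcNegative = 0.4, seed = 1L,
                            task = "identification",
                            idPrefix = c("pos", "neg")) {
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  if (length < 3) stop("length must be >= 3")
  for (gc in c(gcPositive, gcNegative))
    if (gc < 0 || gc > 1) stop("GC fractions must lie in [0, 1]")
  withSeed(seed, {
    pos <- .randSeqs(nPerClass, length, gcPositive)
    neg <- .randSeqs(nPerClass, length, gcNegative)
  })
  seqs <- c(pos, neg)
  names(seqs) <- c(paste0(idPrefix[1], "_", seq_len(nPerClass)),
                   paste0(idPrefix[2], "_", seq_len(nPerClass)))
  EnhancerSet(seqs, label = rep(c(1L, 0L), each = nPerClass), task = task)
}

.randSeqs <- function(n, L, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A, C, G, T
  m <- matrix(sample(NUCLEOTIDES, n * L, replace = TRUE, prob = p), n, L)
  apply(m, 1, paste0, collapse = "")
}

#' Simulate a benchmark-shaped pair of development and test sets
#'
#' Emulates the structure of the enhancer benchmark: a development set of
#' 1,484 enhancers (742 strong + 742 weak) and 1,484 non-enhancers, and
#' an independent test set of 200 enhancers (100 strong + 100 weak) and
#' 200 non-enhancers, all 200 bp. GC content decreases from strong
#' enhancers to weak enhancers to non-enhancers (defaults 0.60 / 0.50 /
#' 0.40), giving the two tasks separable but unequal difficulty, as in
#' the real data where strength classification is the harder problem.
#'
#' @param seed Integer seed.
#' @param gcStrong,gcWeak,gcNon GC fractions of the three groups.
#' @return Named list of four labeled [EnhancerSet-class] objects:
#'   `identificationDev`, `identificationTest` (enhancer = 1 vs
#'   non-enhancer = 0) and `classificationDev`, `classificationTest`
#'   (strong = 1 vs weak = 0).
#' @export
simulateBenchmarkMimic <- function(seed = 1L, gcStrong = 0.6, gcWeak = 0.5,
                                   gcNon = 0.4) {
  counts <- list(dev = c(strong = 742L, weak = 742L, non = 1484L),
                 test = c(strong = 100L, weak = 100L, non = 200L))
  groups <- withSeed(seed, {
    g <- list()
    for (split in names(counts)) {
      for (grp in names(counts[[split]])) {
        gc <- switch(grp, strong = gcStrong, weak = gcWeak, non = gcNon)
        n <- counts[[split]][[grp]]
        s <- .randSeqs(n, 200L, gc)
        names(s) <- sprintf("%s_%s_%d", split, grp, seq_len(n))
        g[[paste(split, grp, sep = ".")]] <- s
      }
    }
    g
  })
  mk <- function(pos, neg, task)
    EnhancerSet(c(pos, neg),
                label = rep(c(1L, 0L), c(length(pos), length(neg))),
                task = task)
  list(
    identificationDev = mk(c(groups$dev.strong, groups$dev.weak),
                           groups$dev.non, "identification"),
    identificationTest = mk(c(groups$test.strong, groups$test.weak),
                            groups$test.non, "identification"),
    classificationDev = mk(groups$dev.strong, groups$dev.weak,
                           "classification"),
    classificationTest = mk(groups$test.strong, groups$test.weak,
                            "classification"))
}
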
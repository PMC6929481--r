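# Independent brute-force oracle for the positional encoding: for every
# position, re-count matching windows over the whole sequence by direct
# substring comparison. Deliberately naive (O(L^2)) and shares no code
# with encodeSequence().
bruteForceEncode <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  nts <- c("A", "C", "G", "T")
  out <- matrix(0, L, 8, dimnames = list(NULL, c(nts, "x", "y", "z", "t")))
  countWindows <- function(word, k) {
    n <- 0
    for (j in 1:(L - k + 1)) if (substr(s, j, j + k - 1) == word) n <- n + 1
    n
  }
  for (i in 1:L) {
    nt <- substr(s, i, i)
    out[i, match(nt, nts)] <- 1
    out[i, "x"] <- countWindows(nt, 1) / L
    out[i, "y"] <- if (i < L) countWindows(substr(s, i, i + 1), 2) / (L - 1) else 0
    out[i, "z"] <- if (i > 1) countWindows(substr(s, i - 1, i), 2) / (L - 1) else 0
    out[i, "t"] <- if (i < L - 1) countWindows(substr(s, i, i + 2), 3) / (L - 2) else 0
  }
  out
}

randomSeq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# small architecture used throughout the model tests: 32 bp inputs pool
# down to 2 positions x 8 filters = 16 flattened features
tinyConfig <- function(...) {
  cnnConfig(inputLength = 32L, filters = 8L, fcSizes = c(16L, 8L), ...)
}

tinyDataset <- function(nPerClass = 10, seed = 1, gcPos = 0.9, gcNeg = 0.1) {
  simulateDataset(nPerClass, length = 32, gcPositive = gcPos,
                  gcNegative = gcNeg, seed = seed)
}

writeTempFasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
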
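NUCLEOTIDES <- c("A", "C", "G", "T")

#' One-hot code of a nucleotide
#'
#' Fixed channel order A, C, G, T: 'A' -> (1,0,0,0), 'C' -> (0,1,0,0),
#' 'G' -> (0,0,1,0), 'T' -> (0,0,0,1).
#'
#' @param nucleotide Single character, one of A/C/G/T (case-insensitive).
#' @return Named numeric 4-vector with exactly one 1.
#' @export
oneHot <- function(nucleotide) {
  i <- match(toupper(nucleotide), NUCLEOTIDES)
  if (length(i) != 1 || is.na(i))
    stop("nucleotide must be a single character among A, C, G, T")
  setNames(as.numeric(seq_len(4) == i), NUCLEOTIDES)
}

#' Overlapping k-mer counts of a sequence
#'
#' Counts all overlapping windows of size `k` (1, 2 or 3 — the sizes used
#' by the positional encoding) over the whole sequence. Counts sum to
#' `L - k + 1`.
#'
#' @param sequence Character string over A/C/G/T.
#' @param k Window size, 1, 2 or 3.
#' @return Named integer vector of counts for the k-mers present.
#' @examples
#' kmerCounts("ACACA", 3)  # ACA: 2, CAC: 1
#' @export
kmerCounts <- function(sequence, k) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < k) stop("sequence shorter than k")
  starts <- seq_len(L - k + 1)
  kmers <- substring(sequence, starts, starts + k - 1)
  tab <- table(kmers)
  setNames(as.integer(tab), names(tab))
}

#' Positional one-hot and k-mer features at one position
#'
#' For position `i` of a sequence `S` of length `L`, returns the one-hot
#' code of the nucleotide at `i` together with the four whole-sequence
#' occurrence-frequency features anchored there:
#' \describe{
#'   \item{x}{count of the 1-mer `S[i]` in `S`, divided by `L`.}
#'   \item{y}{count of the 2-mer `S[i..i+1]` divided by `L - 1`; 0 at
#'     `i = L`.}
#'   \item{z}{count of the 2-mer `S[i-1..i]` divided by `L - 1`; 0 at
#'     `i = 1`.}
#'   \item{t}{count of the 3-mer `S[i..i+2]` divided by `L - 2`; 0 at
#'     `i >= L - 1`.}
#' }
#' Counts are over all overlapping windows of the full sequence.
#'
#' @param sequence Character string over A/C/G/T, length >= 3.
#' @param i 1-based position.
#' @return List with components `onehot` (4-vector) and `x`, `y`, `z`, `t`.
#' @export
positionalFeatures <- function(sequence, i) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (i < 1 || i > L) stop("position i out of range 1..L")
  m <- encodeSequence(sequence)
  list(onehot = m[i, 1:4], x = m[i, "x"], y = m[i, "y"], z = m[i, "z"],
       t = m[i, "t"])
}

#' Encode a sequence as an L x 8 feature matrix
#'
#' Row `i` is the concatenation of the one-hot code of nucleotide `i`
#' (channels A, C, G, T) and the positional k-mer frequencies `x`, `y`,
#' `z`, `t` (see [positionalFeatures()]). A 200 bp sequence therefore
#' becomes a 200 x 8 matrix. Defined for any length >= 3.
#'
#' @param sequence Character string, [Biostrings::DNAString], or a
#'   length-1 [Biostrings::DNAStringSet].
#' @return Numeric `L x 8` matrix, columns `A,C,G,T,x,y,z,t`.
#' @examples
#' dim(encodeSequence(strrep("ACGT", 50)))  # 200 x 8
#' @export
encodeSequence <- function(sequence) {
  if (is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1)
    sequence <- as.character(sequence[[1]])
  } else if (is(sequence, "DNAString")) {
    sequence <- as.character(sequence)
  }
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < 3) stop("sequence must be at least 3 bases long")
  code <- match(strsplit(s, "", fixed = TRUE)[[1]], NUCLEOTIDES)
  if (anyNA(code))
    stop("sequence contains characters outside {A,C,G,T}")

  oh <- matrix(0, L, 4, dimnames = list(NULL, NUCLEOTIDES))
  oh[cbind(seq_len(L), code)] <- 1

  # integer codes of the k-mer starting at each eligible position
  c1 <- code
  c2 <- (code[-L] - 1L) * 4L + code[-1L]                       # length L-1
  c3 <- (code[seq_len(L - 2)] - 1L) * 16L +
        (code[seq(2, L - 1)] - 1L) * 4L + code[seq(3, L)]      # length L-2

  n1 <- tabulate(c1, 4L)
  n2 <- tabulate(c2, 16L)
  n3 <- tabulate(c3, 64L)

  x <- n1[c1] / L
  y <- c(n2[c2], 0) / (L - 1)
  z <- c(0, n2[c2]) / (L - 1)
  t <- c(n3[c3], 0, 0) / (L - 2)

  cbind(oh, x = x, y = y, z = z, t = t)
}

#' Encode every sequence of a dataset
#'
#' @param x An [EnhancerSet-class], [Biostrings::DNAStringSet] or
#'   character vector of same-length sequences.
#' @return Numeric array `n x L x 8`; `dimnames[[1]]` carries record ids.
#' @export
encodeDataset <- function(x) {
  if (is(x, "EnhancerSet")) x <- sequences(x)
  if (is(x, "DNAStringSet")) {
    ids <- names(x)
    x <- as.character(x)
  } else {
    ids <- names(x)
  }
  n <- length(x)
  if (!n) stop("no sequences to encode")
  L <- nchar(x[[1]])
  out <- array(0, dim = c(n, L, 8L),
               dimnames = list(ids, NULL, c(NUCLEOTIDES, "x", "y", "z", "t")))
  for (i in seq_len(n)) out[i, , ] <- encodeSequence(x[[i]])
  out
}
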
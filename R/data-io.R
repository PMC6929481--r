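#' Read DNA sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a [Biostrings::DNAStringSet],
#' uppercasing sequences and validating that every character is one of
#' A, C, G, T. Records keep their file order; the id is the header text up
#' to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), fa)
#' readFastaRecords(fa)
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) stop("empty FASTA file: ", path)
  first <- nonEmpty[1]
  if (!startsWith(lines[first], ">"))
    stop(sprintf("malformed FASTA in '%s': line %d does not start a record ('>')",
                 path, first))
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  bad <- regexpr("[^ACGT]", chars)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("sequence '%s' contains invalid character '%s' (only A/C/G/T allowed)",
                 ids[i], substr(chars[i], bad[i], bad[i])))
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param x An [EnhancerSet-class], [Biostrings::DNAStringSet] or named
#'   character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(x, path) {
  if (is(x, "EnhancerSet")) x <- sequences(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Load a positive/negative FASTA pair as a labeled benchmark dataset
#'
#' Reads two FASTA files, labels records from `posPath` 1 and from
#' `negPath` 0, and returns a validated [EnhancerSet-class]. In benchmark
#' mode (`expectedLength = 200`, the benchmark fragment length) any
#' sequence of a different length is an error. Ids duplicated across the
#' two files are disambiguated with a `pos_`/`neg_` prefix and a warning.
#'
#' @param posPath FASTA of positive sequences (enhancers, or strong
#'   enhancers for the classification task).
#' @param negPath FASTA of negative sequences (non-enhancers, or weak
#'   enhancers).
#' @param task `"identification"` or `"classification"`.
#' @param expectedLength Required sequence length in bases; `NULL` to
#'   accept any common length.
#' @return An [EnhancerSet-class] with all records labeled.
#' @export
loadBenchmark <- function(posPath, negPath,
                          task = c("identification", "classification"),
                          expectedLength = 200L) {
  task <- match.arg(task)
  pos <- readFastaRecords(posPath)
  neg <- readFastaRecords(negPath)
  if (!is.null(expectedLength)) {
    for (s in list(pos, neg)) {
      w <- Biostrings::width(s)
      if (any(w != expectedLength))
        stop(sprintf("sequence '%s' has length %d; benchmark mode requires %d bp",
                     names(s)[w != expectedLength][1],
                     w[w != expectedLength][1], expectedLength))
    }
  }
  if (any(names(pos) %in% names(neg))) {
    warning("ids duplicated across the positive and negative files; ",
            "disambiguating with 'pos_'/'neg_' prefixes")
    names(pos) <- paste0("pos_", names(pos))
    names(neg) <- paste0("neg_", names(neg))
  }
  EnhancerSet(c(pos, neg),
              label = rep(c(1L, 0L), c(length(pos), length(neg))),
              task = task)
}

#' Stratified k-fold partition of a labeled dataset
#'
#' Assigns every record to one of `k` folds with exact stratification:
#' within each class the records are shuffled (driven by `seed`) and dealt
#' into folds whose sizes differ by at most one. The same dataset, `k` and
#' seed always give the identical assignment.
#'
#' @param dataset A fully labeled [EnhancerSet-class].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the within-class shuffle.
#' @return A [FoldAssignment-class].
#' @examples
#' es <- simulateDataset(nPerClass = 10, length = 20, seed = 1)
#' table(foldIndices(stratifiedPartition(es, k = 5, seed = 3)),
#'       classLabels(es))
#' @export
stratifiedPartition <- function(dataset, k = 5L, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  lab <- classLabels(dataset)
  if (anyNA(lab)) stop("all records must be labeled")
  fold <- integer(length(lab))
  names(fold) <- names(lab)
  withSeed(seed, {
    for (cls in sort(unique(lab))) {
      idx <- which(lab == cls)
      nc <- length(idx)
      if (nc < k)
        stop(sprintf("class %d has %d records, fewer than k = %d", cls, nc, k))
      sizes <- rep(nc %/% k, k)
      extra <- nc %% k
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      fold[sample(idx)] <- rep(seq_len(k), sizes)
    }
  })
  new("FoldAssignment", k = k, fold = fold, seed = as.integer(seed))
}

#' Export a fold assignment as a two-column table
#'
#' Writes tab-separated `id`, `fold` rows.
#'
#' @param folds A [FoldAssignment-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFoldAssignment <- function(folds, path) {
  df <- data.frame(id = names(foldIndices(folds)), fold = foldIndices(folds),
                   row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` with the given seed while leaving the caller's RNG
# stream untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
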
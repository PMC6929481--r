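#' Construct an EnhancerSet
#'
#' Bundles DNA sequences with optional binary labels and a task tag into a
#' validated [EnhancerSet-class]. Sequences are uppercased; any character
#' outside A/C/G/T (including N) is rejected, because the positional
#' encoding defines channels for exactly the four nucleotides.
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character vector
#'   of same-length DNA sequences.
#' @param label Optional vector of 0/1 labels (or `NA`), recycled `NA` if
#'   omitted.
#' @param task `"identification"`, `"classification"` or `""`.
#' @return An [EnhancerSet-class].
#' @examples
#' es <- EnhancerSet(c(s1 = "ACGTACGT", s2 = "GGGGCCCC"), label = c(1, 0))
#' classLabels(es)
#' @export
EnhancerSet <- function(sequences, label = NULL, task = "") {
  if (is.character(sequences)) {
    nm <- names(sequences)
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
    names(sequences) <- nm
  }
  if (is.null(names(sequences)) && length(sequences))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  if (is.null(label)) label <- rep(NA_integer_, length(sequences))
  new("EnhancerSet", sequences = sequences, label = as.integer(label),
      task = task)
}

#' @describeIn EnhancerSet The underlying [Biostrings::DNAStringSet].
#' @param x An `EnhancerSet`.
#' @export
setMethod("sequences", "EnhancerSet", function(x) x@sequences)

#' @describeIn EnhancerSet Integer 0/1/`NA` label per record, named by id.
#' @export
setMethod("classLabels", "EnhancerSet",
          function(x) setNames(x@label, names(x@sequences)))

#' @describeIn EnhancerSet The task tag.
#' @export
setMethod("taskType", "EnhancerSet", function(x) x@task)

#' @export
setMethod("length", "EnhancerSet", function(x) length(x@sequences))

#' @export
setMethod("names", "EnhancerSet", function(x) names(x@sequences))

#' @export
setMethod("[", "EnhancerSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  initialize(x, sequences = x@sequences[i], label = x@label[i])
})

setMethod("show", "EnhancerSet", function(object) {
  n <- length(object)
  w <- if (n) unique(Biostrings::width(object@sequences)) else NA_integer_
  cat(sprintf("EnhancerSet of %d sequence%s", n, if (n == 1) "" else "s"))
  if (n) cat(sprintf(" (length %d bp)", w))
  if (nzchar(object@task)) cat(sprintf(", task: %s", object@task))
  cat("\n")
  if (n) {
    tab <- table(factor(object@label, levels = c(1L, 0L)), useNA = "ifany")
    cat(sprintf("  positives: %d  negatives: %d  unlabeled: %d\n",
                tab[["1"]], tab[["0"]], sum(is.na(object@label))))
  }
  invisible(object)
})

#' @describeIn stratifiedPartition Fold index per record, named by id.
#' @export
setMethod("foldIndices", "FoldAssignment", function(x) x@fold)

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d records in %d folds (seed %d)\n",
              length(object@fold), object@k, object@seed))
  print(table(fold = object@fold))
  invisible(object)
})
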
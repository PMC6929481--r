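#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("taskType", function(x) standardGeneric("taskType"))

#' @export
setGeneric("foldIndices", function(x) standardGeneric("foldIndices"))

#' Predicted probabilities of a single CNN member
#'
#' @param model A [CNNModel-class].
#' @param x Encoded input: an `n x L x 8` array from [encodeDataset()], a
#'   single `L x 8` matrix from [encodeSequence()], or an [EnhancerSet-class]
#'   / [Biostrings::DNAStringSet] / character vector of sequences (encoded
#'   on the fly).
#' @return Numeric vector of probabilities in `[0, 1]`, one per input
#'   sequence, order preserved. Inference uses the frozen batch-norm
#'   running statistics, so repeated calls are identical.
#' @export
setGeneric("predictProba", function(model, x) standardGeneric("predictProba"))
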
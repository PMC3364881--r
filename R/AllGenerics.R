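#' @describeIn ProfileHMM-class number of match states
#' @param x,object A `ProfileHMM`.
#' @export
setGeneric("hmmLength", function(x) standardGeneric("hmmLength"))

#' @export
setMethod("hmmLength", "ProfileHMM", function(x) nrow(x@matchEmissions))

#' @describeIn ProfileHMM-class model name
#' @export
setGeneric("hmmName", function(x) standardGeneric("hmmName"))

#' @export
setMethod("hmmName", "ProfileHMM", function(x) x@name)

#' @describeIn ProfileHMM-class `TRUE` once [calibrate()] has stored Gumbel
#'   parameters
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' @export
setMethod("isCalibrated", "ProfileHMM", function(x) length(x@calibration) == 2L)

#' @describeIn ProfileHMM-class fitted Gumbel `c(mu, lambda)` or `numeric(0)`
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @export
setMethod("calibration", "ProfileHMM", function(x) x@calibration)

#' @describeIn ProfileHMM-class match-emission probability matrix
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))

#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmissions)

#' @export
setMethod("show", "ProfileHMM", function(object) {
    cal <- if (isCalibrated(object)) {
        sprintf("calibrated (mu=%.3f, lambda=%.3f)",
                object@calibration[["mu"]], object@calibration[["lambda"]])
    } else "uncalibrated"
    cat(sprintf("ProfileHMM '%s': %d match states, %s\n",
                object@name, hmmLength(object), cal))
})

#' @describeIn BlockSet-class list of member profile HMMs, in block order
#' @param x,object A `BlockSet`.
#' @export
setGeneric("blockHMMs", function(x) standardGeneric("blockHMMs"))

#' @export
setMethod("blockHMMs", "BlockSet", function(x) x@hmms)

#' @describeIn BlockSet-class source-window table (`index`, `colStart`,
#'   `colEnd`)
#' @export
setGeneric("blockInfo", function(x) standardGeneric("blockInfo"))

#' @export
setMethod("blockInfo", "BlockSet", function(x) x@blockInfo)

#' @export
setMethod("length", "BlockSet", function(x) length(x@hmms))

#' @export
setMethod("show", "BlockSet", function(object) {
    ncal <- sum(vapply(object@hmms, isCalibrated, logical(1)))
    cat(sprintf("BlockSet of %d block HMMs (%d calibrated)\n",
                length(object@hmms), ncal))
})

#' @describeIn AnnotatedAlignment-class aligned sequences as an
#'   `AAStringSet`
#' @param x,object An `AnnotatedAlignment`.
#' @export
setGeneric("alignedSequences", function(x) standardGeneric("alignedSequences"))

#' @export
setMethod("alignedSequences", "AnnotatedAlignment", function(x) x@sequences)

#' @describeIn AnnotatedAlignment-class per-sequence exon boundaries
#'   (ungapped residue counts before each boundary)
#' @export
setGeneric("exonBoundaries", function(x) standardGeneric("exonBoundaries"))

#' @export
setMethod("exonBoundaries", "AnnotatedAlignment", function(x) {
    ids <- names(x@sequences)
    b <- setNames(vector("list", length(ids)), ids)
    for (id in ids)
        b[[id]] <- if (id %in% names(x@boundaries))
            as.integer(x@boundaries[[id]]) else integer(0)
    b
})

#' @export
setMethod("show", "AnnotatedAlignment", function(object) {
    cat(sprintf("AnnotatedAlignment: %d sequences x %d columns, %d with exon boundaries\n",
                length(object@sequences), Biostrings::width(object@sequences)[1],
                sum(lengths(object@boundaries) > 0)))
})

#' @export
setMethod("show", "BlockDefinition", function(object) {
    cat(sprintf("BlockDefinition #%d: columns %d-%d (conservation %.3f)\n",
                object@index, object@colStart, object@colEnd, object@score))
})
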
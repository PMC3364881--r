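#' AnnotatedAlignment: a protein alignment with exon-boundary annotations
#'
#' Holds an aligned set of protein sequences together with, for each
#' sequence, the positions of exon boundaries in ungapped residue
#' coordinates.  A boundary value `b` counts the residues preceding it:
#' it sits immediately before residue `b + 1` of the ungapped sequence.
#' Valid values run from 0 to the ungapped length (the two extremes are
#' vacuous but permitted).
#'
#' @slot sequences An [Biostrings::AAStringSet] of equal-width aligned
#'   sequences (gap character `-`).
#' @slot boundaries Named list of strictly increasing integer vectors,
#'   one per sequence id; sequences without annotations get `integer(0)`.
#' @export
setClass("AnnotatedAlignment",
    representation(sequences = "AAStringSet", boundaries = "list"))

setValidity("AnnotatedAlignment", function(object) {
    s <- object@sequences
    if (length(s) < 2L) return("need at least 2 sequences")
    w <- Biostrings::width(s)
    if (length(unique(w)) != 1L) return("ragged alignment: unequal widths")
    if (w[1] < 1L) return("alignment width must be >= 1")
    ids <- names(s)
    if (is.null(ids) || anyDuplicated(ids)) return("sequences must have unique names")
    if (!all(names(object@boundaries) %in% ids))
        return("boundary ids absent from alignment")
    ung <- setNames(vapply(seq_along(s), function(i) {
        sum(strsplit(as.character(s[[i]]), "")[[1]] != "-")
    }, integer(1)), ids)
    for (id in names(object@boundaries)) {
        b <- object@boundaries[[id]]
        if (length(b) == 0L) next
        if (any(b != as.integer(b)) || is.unsorted(b, strictly = TRUE))
            return(sprintf("boundaries for '%s' must be strictly increasing integers", id))
        if (any(b < 0L) || any(b > ung[[id]]))
            return(sprintf("boundary out of range for sequence '%s' (ungapped length %d)",
                           id, ung[[id]]))
    }
    TRUE
})

#' BlockDefinition: one conserved block of an alignment
#'
#' A contiguous column window of an [AnnotatedAlignment] chosen so that its
#' projection onto every member sequence crosses no annotated exon boundary.
#' Blocks are ordered; the ordinal `index` encodes the expected genomic
#' order of their homologous regions.
#'
#' @slot index Integer ordinal (1-based) giving the block's position in the
#'   expected genomic order.
#' @slot colStart,colEnd Integer alignment-column interval, 1-based closed.
#' @slot alignment The sub-[AnnotatedAlignment] over those columns.
#' @slot score Conservation score of the window (mean majority-residue
#'   identity per column, gaps scoring 0).
#' @export
setClass("BlockDefinition",
    representation(index = "integer", colStart = "integer",
                   colEnd = "integer", alignment = "AnnotatedAlignment",
                   score = "numeric"))

setValidity("BlockDefinition", function(object) {
    if (object@colStart < 1L || object@colEnd < object@colStart)
        return("invalid column interval")
    TRUE
})

#' ProfileHMM: a position-specific probabilistic model of one block
#'
#' A Plan7-style profile hidden Markov model with per-column match, insert
#' and delete states, scored against targets in local mode (uniform entry
#' over match states, free exit).  Optionally carries the location and
#' scale of the Gumbel null-score distribution estimated by [calibrate()].
#'
#' @slot name Model name.
#' @slot matchEmissions `L x 20` matrix; each row a probability
#'   distribution over residues (columns in `ACDEFGHIKLMNPQRSTVWY` order).
#' @slot insertEmissions Length-20 probability vector shared by all insert
#'   states (background-style).
#' @slot transitions `(L-1) x 7` matrix with columns
#'   `MM, MI, MD, IM, II, DM, DD`; the three groups `M->{M,I,D}`,
#'   `I->{M,I}` and `D->{M,D}` each sum to 1 row-wise.
#' @slot background Length-20 background distribution used for log-odds.
#' @slot calibration Either `numeric(0)` (uncalibrated) or
#'   `c(mu = , lambda = )` of the fitted Gumbel.
#' @export
setClass("ProfileHMM",
    representation(name = "character", matchEmissions = "matrix",
                   insertEmissions = "numeric", transitions = "matrix",
                   background = "numeric", calibration = "numeric"))

setValidity("ProfileHMM", function(object) {
    tol <- 1e-9
    M <- object@matchEmissions
    L <- nrow(M)
    if (is.null(L) || L < 1L) return("need at least one match state")
    if (ncol(M) != 20L) return("matchEmissions must have 20 columns")
    if (any(abs(rowSums(M) - 1) > tol)) return("match emission rows must sum to 1")
    if (any(M < -tol)) return("negative match emission")
    if (abs(sum(object@insertEmissions) - 1) > tol || length(object@insertEmissions) != 20L)
        return("insertEmissions must be a 20-vector summing to 1")
    if (abs(sum(object@background) - 1) > tol || length(object@background) != 20L)
        return("background must be a 20-vector summing to 1")
    if (any(object@background <= 0)) return("background frequencies must be positive")
    tr <- object@transitions
    if (L > 1L) {
        if (nrow(tr) != L - 1L || ncol(tr) != 7L)
            return("transitions must be (L-1) x 7")
        grp <- list(c(1, 2, 3), c(4, 5), c(6, 7))
        for (g in grp)
            if (any(abs(rowSums(tr[, g, drop = FALSE]) - 1) > tol))
                return("transition groups must sum to 1")
        if (any(tr < -tol)) return("negative transition probability")
    }
    cal <- object@calibration
    if (length(cal) != 0L) {
        if (length(cal) != 2L || !all(c("mu", "lambda") %in% names(cal)))
            return("calibration must be c(mu=, lambda=)")
        if (cal[["lambda"]] <= 0) return("calibration lambda must be > 0")
    }
    TRUE
})

#' BlockSet: an ordered collection of block profile HMMs
#'
#' Wraps the profile HMMs built from an ordered list of conserved blocks.
#' The list order encodes expected genomic order; the k-of-n candidate
#' rule in [callCandidates()] tests collinearity against it.
#'
#' @slot hmms List of [ProfileHMM-class] objects, one per block, in block
#'   order.
#' @slot blockInfo `data.frame` with columns `index`, `colStart`, `colEnd`
#'   describing the source alignment windows.
#' @export
setClass("BlockSet",
    representation(hmms = "list", blockInfo = "data.frame"))

setValidity("BlockSet", function(object) {
    if (length(object@hmms) < 1L) return("empty BlockSet")
    if (!all(vapply(object@hmms, is, logical(1), "ProfileHMM")))
        return("hmms must all be ProfileHMM")
    if (nrow(object@blockInfo) != length(object@hmms))
        return("blockInfo rows must match hmms")
    TRUE
})
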
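#' @useDynLib dscamtools, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats optim runif setNames complete.cases
#' @importFrom utils write.table read.table head tail
NULL

# canonical residue order used throughout (match-emission columns)
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Robinson-Robinson background amino-acid frequencies
#'
#' The standard background distribution used for profile log-odds scores,
#' ordered as `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' sum(robinsonBackground())
robinsonBackground <- function() {
    setNames(c(0.07805, 0.01925, 0.05364, 0.06295, 0.03856,
               0.07377, 0.02199, 0.05142, 0.05744, 0.09019,
               0.02243, 0.04487, 0.05203, 0.04264, 0.05129,
               0.07120, 0.05841, 0.06441, 0.01330, 0.03216),
             AA_ALPHABET)
}

#' Uniform amino-acid background
#'
#' @return Named numeric vector of length 20, each 1/20.
#' @export
uniformBackground <- function() {
    setNames(rep(1 / 20, 20), AA_ALPHABET)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.  All stochastic operations in the package funnel
# through this so that (spec, seed) -> identical bytes.
with_seed <- function(seed, expr) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# derive a distinct 32-bit sub-seed from a master seed and a stream label
derive_seed <- function(seed, stream) {
    s <- (as.double(seed) * 48271 + sum(utf8ToInt(as.character(stream)))) %%
        2147483647
    as.integer(max(1, s))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
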
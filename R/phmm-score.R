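#' Score a sequence against a profile HMM (Viterbi)
#'
#' Best local-alignment log-odds score, in bits, of an amino-acid
#' sequence under the model, found by Viterbi dynamic programming.
#' Unknown residues (`X` or any non-standard letter) emit at background
#' (log-odds 0).
#'
#' @param hmm A [ProfileHMM-class].
#' @param seq Amino-acid string.
#' @return List with `score` (bits), `start`, `end` (1-based closed
#'   residue interval of the aligned region; `start = 1, end = 0` for an
#'   empty sequence, with score `-Inf`).
#' @export
#' @examples
#' aln <- new("AnnotatedAlignment",
#'            sequences = Biostrings::AAStringSet(c(a = "ACDEF", b = "ACDEF")),
#'            boundaries = list())
#' h <- buildProfile(aln, alpha = 0)
#' viterbi(h, "ACDEF")$score > viterbi(h, "FEDCA")$score
viterbi <- function(hmm, seq) {
    stopifnot(is(hmm, "ProfileHMM"))
    seq <- as.character(seq)
    if (nchar(seq) == 0L)
        return(list(score = -Inf, start = 1L, end = 0L))
    r <- viterbiBatch(hmm, seq)
    list(score = r[1, 1], start = as.integer(r[1, 2]) + 1L,
         end = as.integer(r[1, 3]))
}

# vectorized Viterbi over many segments; returns matrix (score, start0, end0)
# with 0-based half-open residue intervals
viterbiBatch <- function(hmm, seqs) {
    n <- nchar(seqs)
    concat <- paste(seqs, collapse = "")
    starts <- cumsum(c(0L, n[-length(n)]))
    lo <- hmm_lodds(hmm)
    .cpp_viterbi_batch(concat, as.integer(starts), as.integer(n),
                       lo$matchLO, lo$transLO, lo$entryLO)
}

#' Score a sequence against a profile HMM (forward)
#'
#' Log-sum-of-odds over all local alignments, in bits.  Always at least
#' the [viterbi()] score of the same sequence, since the optimal path is
#' one term of the sum.
#'
#' @inheritParams viterbi
#' @return Forward bit score (scalar; `-Inf` for an empty sequence).
#' @export
forwardScore <- function(hmm, seq) {
    stopifnot(is(hmm, "ProfileHMM"))
    seq <- as.character(seq)
    if (nchar(seq) == 0L) return(-Inf)
    lo <- hmm_lodds(hmm)
    .cpp_forward(seq, lo$matchLO, lo$transLO, lo$entryLO)
}

#' Calibrate a profile HMM's score null distribution
#'
#' Scores `nSamples` i.i.d. background sequences of length `sampleLen`
#' with [viterbi()] and fits a Gumbel (extreme-value) distribution
#' \deqn{P(S > s) = 1 - \exp(-e^{-\lambda (s - \mu)})}
#' by maximum likelihood.  The fitted `(mu, lambda)` are stored on the
#' model and drive [evalue()].
#'
#' @param x A [ProfileHMM-class] or [BlockSet-class] (calibrates every
#'   member model, deriving one sub-seed per block).
#' @param nSamples Number of null sequences (>= 100; default 5000, the
#'   sample size classic HMM calibration used).
#' @param sampleLen Null sequence length in residues (default 100).
#' @param seed Integer seed; same seed, same `(mu, lambda)`.
#' @param ... Unused.
#' @return The input object with calibration parameters set.
#' @export
setGeneric("calibrate", function(x, ...) standardGeneric("calibrate"))

#' @rdname calibrate
#' @export
setMethod("calibrate", "ProfileHMM",
    function(x, nSamples = 5000L, sampleLen = 100L, seed = 1L, ...) {
    stopifnot(nSamples >= 100L, sampleLen >= 1L)
    seqs <- with_seed(seed, {
        vapply(seq_len(nSamples), function(i)
            paste(sample(AA_ALPHABET, sampleLen, replace = TRUE,
                         prob = x@background), collapse = ""),
            character(1))
    })
    scores <- viterbiBatch(x, seqs)[, 1]
    x@calibration <- fit_gumbel(scores)
    x
})

#' @rdname calibrate
#' @export
setMethod("calibrate", "BlockSet",
    function(x, nSamples = 5000L, sampleLen = 100L, seed = 1L, ...) {
    x@hmms <- lapply(seq_along(x@hmms), function(i)
        calibrate(x@hmms[[i]], nSamples = nSamples, sampleLen = sampleLen,
                  seed = derive_seed(seed, paste0("cal", i))))
    x
})

# maximum-likelihood Gumbel fit; moments initialisation, BFGS refinement
fit_gumbel <- function(scores) {
    scores <- scores[is.finite(scores)]
    if (length(scores) < 50L || stats::sd(scores) < 1e-8)
        stopf("calibration error: degenerate score variance")
    lambda0 <- pi / (stats::sd(scores) * sqrt(6))
    mu0 <- mean(scores) - 0.5772156649 / lambda0
    nll <- function(p) {
        lam <- exp(p[2])
        z <- lam * (scores - p[1])
        -length(scores) * log(lam) + sum(z) + sum(exp(-z))
    }
    fit <- optim(c(mu0, log(lambda0)), nll, method = "BFGS")
    c(mu = fit$par[1], lambda = exp(fit$par[2]))
}

#' Gumbel tail probability of a bit score
#'
#' @param score Bit score(s).
#' @param hmm A calibrated [ProfileHMM-class].
#' @return `P(S > score)` under the fitted null, computed stably in the
#'   far tail.
#' @export
gumbelPValue <- function(score, hmm) {
    if (!isCalibrated(hmm)) stopf("profile '%s' is not calibrated", hmm@name)
    mu <- hmm@calibration[["mu"]]; lambda <- hmm@calibration[["lambda"]]
    t <- exp(-lambda * (score - mu))
    -expm1(-t)
}

#' E-value of a bit score
#'
#' Expected number of hits of at least `score` in a search over
#' `dbSize` scanned segments:
#' \deqn{E = dbSize \times (1 - \exp(-e^{-\lambda (score - \mu)}))}
#' Strictly decreasing in `score` and linear in `dbSize`.
#'
#' @param score Bit score(s).
#' @param hmm A calibrated [ProfileHMM-class].
#' @param dbSize Number of translated segments scanned (>= 1).
#' @return E-value(s), same length as `score`.
#' @export
#' @examples
#' ## at score = mu the tail probability is 1 - exp(-1)
evalue <- function(score, hmm, dbSize) {
    stopifnot(dbSize >= 1)
    dbSize * gumbelPValue(score, hmm)
}
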
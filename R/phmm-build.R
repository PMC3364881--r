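#' Build a profile HMM from a conserved block
#'
#' Estimates a Plan7-style profile from a block sub-alignment.  Columns
#' with gap fraction below 0.5 become match states; the remaining columns
#' feed insert states.  Match emissions use background-proportional
#' pseudocounts:
#' \deqn{e_j(a) = (c_j(a) + \alpha\, bg(a)) / (n_j + \alpha)}
#' where `c_j(a)` counts residue `a` in match column `j` and `n_j` the
#' non-gap residues there.  Transition probabilities are estimated from
#' the observed per-sequence state paths with the same pseudocount rule
#' (uniform prior within each transition group).  The model is scored in
#' local mode: uniform entry over match states, free exit.
#'
#' @param block A [BlockDefinition-class] or [AnnotatedAlignment-class].
#' @param alpha Pseudocount weight (>= 0).  With `alpha = 0` unseen
#'   residues get probability 0, scored as an effectively infinite
#'   penalty.
#' @param background Length-20 background distribution
#'   (default [robinsonBackground()]).
#' @param name Model name; defaults to `block<index>` when a
#'   `BlockDefinition` is given.
#' @return An uncalibrated [ProfileHMM-class].
#' @export
buildProfile <- function(block, alpha = 1, background = robinsonBackground(),
                         name = NULL) {
    if (is(block, "BlockDefinition")) {
        if (is.null(name)) name <- sprintf("block%d", block@index)
        aln <- block@alignment
    } else if (is(block, "AnnotatedAlignment")) {
        if (is.null(name)) name <- "profile"
        aln <- block
    } else stopf("block must be BlockDefinition or AnnotatedAlignment")
    stopifnot(alpha >= 0, length(background) == 20L)
    background <- background / sum(background)

    mat <- do.call(rbind, strsplit(as.character(aln@sequences), ""))
    nseq <- nrow(mat); W <- ncol(mat)
    gapfrac <- colMeans(mat == "-")
    is_match <- gapfrac < 0.5
    L <- sum(is_match)
    if (L == 0L) stopf("profile build error: no column has gap fraction < 0.5")

    match_cols <- which(is_match)
    M <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
    for (j in seq_len(L)) {
        col <- mat[, match_cols[j]]
        res <- col[col != "-"]
        res <- res[res %in% AA_ALPHABET]
        cnt <- table(factor(res, levels = AA_ALPHABET))
        M[j, ] <- (as.numeric(cnt) + alpha * background) /
            (length(res) + alpha)
    }

    # state path per sequence over match/insert columns, then pooled
    # transition counts per inter-match junction
    tr_names <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
    counts <- matrix(0, max(L - 1L, 1L), 7L, dimnames = list(NULL, tr_names))
    if (L > 1L) {
        col_state <- ifelse(is_match, "m", "i")
        junction <- cumsum(is_match)  # insert columns belong after match j
        for (s in seq_len(nseq)) {
            row <- mat[s, ]
            for (j in seq_len(L - 1L)) {
                from <- if (row[match_cols[j]] == "-") "D" else "M"
                to <- if (row[match_cols[j + 1L]] == "-") "D" else "M"
                ins_cols <- which(col_state == "i" & junction == j)
                n_ins <- sum(row[ins_cols] != "-")
                if (n_ins > 0L && from == "M") {
                    counts[j, "MI"] <- counts[j, "MI"] + 1
                    counts[j, "II"] <- counts[j, "II"] + (n_ins - 1L)
                    counts[j, paste0("I", to)] <- counts[j, paste0("I", to)] + 1
                } else {
                    counts[j, paste0(from, to)] <- counts[j, paste0(from, to)] + 1
                }
            }
        }
    }
    groups <- list(MM = c("MM", "MI", "MD"), IM = c("IM", "II"),
                   DM = c("DM", "DD"))
    trans <- matrix(0, max(L - 1L, 1L), 7L, dimnames = list(NULL, tr_names))
    for (g in groups) {
        prior <- 1 / length(g)
        tot <- rowSums(counts[, g, drop = FALSE])
        for (nm in g) {
            est <- (counts[, nm] + alpha * prior) / (tot + alpha)
            est[tot + alpha == 0] <- prior
            trans[, nm] <- est
        }
    }
    if (L == 1L) trans <- matrix(numeric(0), 0L, 7L,
                                 dimnames = list(NULL, tr_names))

    new("ProfileHMM", name = name, matchEmissions = M,
        insertEmissions = background, transitions = trans,
        background = background, calibration = numeric(0))
}

# log2-odds views consumed by the C++ kernels; column 21 is 'X'
hmm_lodds <- function(hmm) {
    L <- hmmLength(hmm)
    lo <- log2(sweep(hmm@matchEmissions, 2, hmm@background, "/"))
    lo[lo < -1e30 | !is.finite(lo)] <- -1e30
    matchLO <- cbind(lo, 0)
    transLO <- if (L > 1L) {
        t <- log2(hmm@transitions)
        t[t < -1e30 | !is.finite(t)] <- -1e30
        t
    } else matrix(0, 0L, 7L)
    list(matchLO = matchLO, transLO = transLO, entryLO = log2(1 / L))
}
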
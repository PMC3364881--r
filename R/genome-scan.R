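#' Six-frame translation of a scaffold into stop-free segments
#'
#' Translates a nucleotide sequence in all six reading frames (three
#' forward, three on the reverse complement), splits each conceptual
#' translation at stop codons and returns every stop-free segment of at
#' least one residue together with its forward-strand nucleotide
#' coordinates.  Codons containing `N` translate to `X`.
#'
#' @param scaffold A `DNAString`, character scalar, or length-1
#'   `DNAStringSet` over `A,C,G,T,N`.
#' @param geneticCode A named genetic code as from
#'   [Biostrings::getGeneticCode()] (standard code by default).
#' @param id Scaffold id used in the output (default `"scaffold"` or the
#'   input name).
#' @return `data.frame` with columns `seqnames`, `strand` (`+`/`-`),
#'   `frame` (0-2, offset from the 5' end of the read strand), `aa`
#'   (segment amino acids), `nt_start`, `nt_end` (0-based half-open,
#'   forward strand; always `nt_end - nt_start == 3 * nchar(aa)`).
#'   Sequences shorter than 3 nt give zero rows.
#' @export
#' @examples
#' sixFrameTranslate("ATGAAA")[, c("strand", "frame", "aa")]
sixFrameTranslate <- function(scaffold, geneticCode = Biostrings::GENETIC_CODE,
                              id = NULL) {
    if (is(scaffold, "DNAStringSet")) {
        stopifnot(length(scaffold) == 1L)
        if (is.null(id)) id <- names(scaffold)
        scaffold <- scaffold[[1]]
    }
    if (is.character(scaffold)) scaffold <- Biostrings::DNAString(scaffold)
    if (is.null(id)) id <- "scaffold"
    set <- Biostrings::DNAStringSet(list(scaffold))
    names(set) <- id
    six_frame_segments(set, geneticCode = geneticCode)
}

# vectorised six-frame segmentation over a whole DNAStringSet
six_frame_segments <- function(genome, geneticCode = Biostrings::GENETIC_CODE) {
    stopifnot(is(genome, "DNAStringSet"))
    if (is.null(names(genome))) names(genome) <- paste0("scaffold", seq_along(genome))
    widths <- Biostrings::width(genome)
    out <- vector("list", 6L)
    k <- 0L
    for (str in c("+", "-")) {
        dna <- if (str == "+") genome else Biostrings::reverseComplement(genome)
        for (f in 0:2) {
            k <- k + 1L
            n_codon <- pmax((widths - f) %/% 3L, 0L)
            keep <- which(n_codon >= 1L)
            if (length(keep) == 0L) { out[[k]] <- NULL; next }
            sub <- Biostrings::subseq(dna[keep], start = f + 1L,
                                      width = 3L * n_codon[keep])
            aa <- as.character(Biostrings::translate(sub,
                genetic.code = geneticCode, if.fuzzy.codon = "X",
                no.init.codon = TRUE))
            out[[k]] <- split_at_stops(aa, names(genome)[keep], widths[keep],
                                       str, f)
        }
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(seqnames = character(0), strand = character(0),
                          frame = integer(0), aa = character(0),
                          nt_start = integer(0), nt_end = integer(0))
    rownames(res) <- NULL
    res
}

# split frame translations at '*' and map each piece to forward-strand nt
split_at_stops <- function(aa, ids, widths, str, f) {
    parts <- strsplit(aa, "*", fixed = TRUE)
    nparts <- lengths(parts)
    if (sum(nparts) == 0L) return(NULL)
    seg <- unlist(parts, use.names = FALSE)
    lens <- nchar(seg)
    starts <- unlist(lapply(parts, function(p) {
        l <- nchar(p)
        cumsum(c(0L, l[-length(l)] + 1L))  # aa offset within the frame
    }), use.names = FALSE)
    idrep <- rep(ids, nparts)
    wrep <- rep(widths, nparts)
    keep <- lens >= 1L
    if (!any(keep)) return(NULL)
    a0 <- starts[keep]; a1 <- starts[keep] + lens[keep]
    if (str == "+") {
        nt0 <- f + 3L * a0; nt1 <- f + 3L * a1
    } else {
        nt0 <- wrep[keep] - (f + 3L * a1); nt1 <- wrep[keep] - (f + 3L * a0)
    }
    data.frame(seqnames = idrep[keep], strand = str, frame = f,
               aa = seg[keep], nt_start = nt0, nt_end = nt1)
}

# forward-strand nt interval of aa span [u, v) within one segment row
aa_span_to_nt <- function(seg, u, v) {
    if (seg$strand == "+") c(seg$nt_start + 3L * u, seg$nt_start + 3L * v)
    else c(seg$nt_end - 3L * v, seg$nt_end - 3L * u)
}

# Scan one HMM over segment rows, recursively re-scanning the flanks of
# passing hits so that several hits per stop-free segment can be reported.
# dbSize stays the original search size throughout the recursion.
scan_hmm_segments <- function(hmm, segs, eCutoff, dbSize,
                              maxPerSegment = 2L) {
    if (nrow(segs) == 0L) return(NULL)
    # exact score upper bound (entry + best emission per residue; transitions
    # cost <= 0 bits): segments that cannot reach the cutoff are skipped
    if (isCalibrated(hmm)) {
        lo <- hmm_lodds(hmm)
        maxbit <- max(0, max(lo$matchLO[, 1:20]))
        ub <- lo$entryLO + maxbit * nchar(segs$aa)
        segs <- segs[evalue(ub, hmm, dbSize) <= eCutoff, , drop = FALSE]
        if (nrow(segs) == 0L) return(NULL)
    }
    segs$orig <- seq_len(nrow(segs))
    hits <- list()
    taken <- integer(nrow(segs))
    queue <- segs
    while (nrow(queue) > 0L) {
        r <- viterbiBatch(hmm, queue$aa)
        E <- evalue(r[, 1], hmm, dbSize)
        pass <- which(E <= eCutoff & r[, 3] > r[, 2] &
                      taken[queue$orig] < maxPerSegment)
        if (length(pass) == 0L) break
        nextq <- list()
        for (idx in pass) {
            seg <- queue[idx, ]
            if (taken[seg$orig] >= maxPerSegment) next
            a0 <- as.integer(r[idx, 2]); a1 <- as.integer(r[idx, 3])
            nt <- aa_span_to_nt(seg, a0, a1)
            hits[[length(hits) + 1L]] <- data.frame(
                seqnames = seg$seqnames, strand = seg$strand,
                frame = seg$frame, nt_start = nt[1], nt_end = nt[2],
                score = r[idx, 1], evalue = E[idx],
                aaSeq = substring(seg$aa, a0 + 1L, a1))
            taken[seg$orig] <- taken[seg$orig] + 1L
            if (taken[seg$orig] >= maxPerSegment) next
            alen <- nchar(seg$aa)
            if (a0 > 0L) {
                left <- seg
                left$aa <- substring(seg$aa, 1L, a0)
                ntl <- aa_span_to_nt(seg, 0L, a0)
                left$nt_start <- ntl[1]; left$nt_end <- ntl[2]
                nextq[[length(nextq) + 1L]] <- left
            }
            if (a1 < alen) {
                right <- seg
                right$aa <- substring(seg$aa, a1 + 1L, alen)
                ntr <- aa_span_to_nt(seg, a1, alen)
                right$nt_start <- ntr[1]; right$nt_end <- ntr[2]
                nextq[[length(nextq) + 1L]] <- right
            }
        }
        queue <- if (length(nextq)) do.call(rbind, nextq)
                 else queue[0, ]
    }
    if (length(hits) == 0L) return(NULL)
    do.call(rbind, hits)
}

#' Scan a genome with a BlockSet of calibrated profile HMMs
#'
#' Six-frame translates every scaffold, scores every stop-free segment
#' against every block HMM with [viterbi()], converts passing local
#' alignments to forward-strand genomic coordinates, and retains the
#' `topM` best-scoring hits per (scaffold, HMM).  E-values use
#' `dbSize =` the number of translated segments in the search.
#'
#' @param blockset A calibrated [BlockSet-class].
#' @param genome A `DNAStringSet` or path to a multi-FASTA.
#' @param eCutoff Report hits with `E <= eCutoff` (default 0.001, the
#'   block-match threshold used for candidate calling).
#' @param topM Hits retained per (scaffold, HMM) (default 2, matching
#'   the best-two-hits convention for assembling gene models).
#' @param geneticCode Genetic code for translation.
#' @return A [GenomicRanges::GRanges] (1-based coordinates) with metadata
#'   columns `block`, `frame`, `score`, `evalue`, `aaSeq`, sorted by
#'   scaffold name, block index, descending score.  Empty genome gives an
#'   empty `GRanges`.
#' @export
scanGenome <- function(blockset, genome, eCutoff = 0.001, topM = 2L,
                       geneticCode = Biostrings::GENETIC_CODE) {
    stopifnot(is(blockset, "BlockSet"), eCutoff > 0)
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    if (!all(vapply(blockset@hmms, isCalibrated, logical(1))))
        stopf("all block HMMs must be calibrated before scanning")
    if (length(genome) == 0L) return(empty_hits())

    segs <- six_frame_segments(genome, geneticCode = geneticCode)
    dbSize <- max(nrow(segs), 1L)
    all_hits <- list()
    for (b in seq_along(blockset@hmms)) {
        h <- scan_hmm_segments(blockset@hmms[[b]], segs, eCutoff, dbSize,
                               maxPerSegment = topM)
        if (is.null(h)) next
        h$block <- b
        # top-m per scaffold for this HMM
        h <- h[order(h$seqnames, -h$score, h$nt_start), , drop = FALSE]
        keep <- unlist(lapply(split(seq_len(nrow(h)), h$seqnames),
                              function(ix) ix[seq_len(min(topM, length(ix)))]))
        all_hits[[length(all_hits) + 1L]] <- h[sort(keep), , drop = FALSE]
    }
    hits_df_to_granges(do.call(rbind, all_hits))
}

empty_hits <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        block = integer(0), frame = integer(0), score = numeric(0),
        evalue = numeric(0), aaSeq = character(0))
    gr
}

hits_df_to_granges <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(empty_hits())
    df <- df[order(df$seqnames, df$block, -df$score, df$nt_start), ,
             drop = FALSE]
    gr <- GenomicRanges::GRanges(
        seqnames = df$seqnames,
        ranges = IRanges::IRanges(start = df$nt_start + 1L, end = df$nt_end),
        strand = df$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        block = as.integer(df$block), frame = as.integer(df$frame),
        score = df$score, evalue = df$evalue, aaSeq = df$aaSeq)
    GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
    gr
}

# heaviest strictly-collinear subsequence over hits of one scaffold+strand:
# at most one hit per block, block index strictly increasing, nt midpoints
# strictly increasing (+) or decreasing (-); maximises count, tie-break on
# summed bit score.  Returns indices into `ord`-sorted hits.
best_collinear_chain <- function(block, mid, score, decreasing = FALSE) {
    n <- length(block)
    if (n == 0L) return(integer(0))
    m <- if (decreasing) -mid else mid
    ord <- order(block, m, -score)
    b <- block[ord]; mm <- m[ord]; sc <- score[ord]
    cnt <- rep(1L, n); tot <- sc; prev <- rep(0L, n)
    for (i in seq_len(n)) {
        for (j in seq_len(i - 1L)) {
            if (b[j] < b[i] && mm[j] < mm[i]) {
                nc <- cnt[j] + 1L; ns <- tot[j] + sc[i]
                if (nc > cnt[i] || (nc == cnt[i] && ns > tot[i])) {
                    cnt[i] <- nc; tot[i] <- ns; prev[i] <- j
                }
            }
        }
    }
    best <- which(cnt == max(cnt))
    best <- best[which.max(tot[best])]
    chain <- integer(0); i <- best
    while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
    ord[chain]
}

#' Call gene candidates with the ordered k-of-n block rule
#'
#' For each scaffold and strand, finds the largest set of block hits (at
#' most one per block) whose genomic order matches the block order:
#' strictly increasing nt midpoints with block index on the forward
#' strand, strictly decreasing on the reverse.  A candidate is emitted
#' when at least `kMin` blocks are collinear — the conservative k-of-n
#' co-occurrence rule (6 of 10 by default) that separates true
#' Dscam-family loci from stray single-block matches.
#'
#' @param hits `GRanges` from [scanGenome()].
#' @param nBlocks Number of blocks in the scanned BlockSet.
#' @param kMin Minimum collinear blocks required (default 6).
#' @param eCutoff Optional stricter E-value filter applied before
#'   chaining (default `NULL`: use the hits as given).
#' @param sameStrand When `TRUE` (default) candidates are called per
#'   strand; when `FALSE` hits of both strands are pooled and either
#'   genomic orientation may carry the chain.
#' @return `GRanges` of candidates (one per scaffold/strand reaching
#'   `kMin`), sorted by descending `totalScore`, with metadata columns
#'   `matchedInOrder`, `totalScore` and a `GRangesList` column `hits`
#'   holding the member block hits.
#' @export
callCandidates <- function(hits, nBlocks, kMin = 6L, eCutoff = NULL,
                           sameStrand = TRUE) {
    stopifnot(kMin >= 1L, kMin <= nBlocks)
    if (!is.null(eCutoff)) hits <- hits[hits$evalue <= eCutoff]
    if (length(hits) == 0L) return(empty_candidates())

    key <- if (sameStrand)
        paste(GenomeInfoDb::seqnames(hits), BiocGenerics::strand(hits))
    else as.character(GenomeInfoDb::seqnames(hits))
    cands <- list()
    for (grp in split(seq_along(hits), key)) {
        h <- hits[grp]
        mid <- (BiocGenerics::start(h) + BiocGenerics::end(h)) / 2
        if (sameStrand) {
            dec <- as.character(BiocGenerics::strand(h)[1]) == "-"
            chain <- best_collinear_chain(h$block, mid, h$score, dec)
        } else {
            up <- best_collinear_chain(h$block, mid, h$score, FALSE)
            dn <- best_collinear_chain(h$block, mid, h$score, TRUE)
            chain <- if (length(dn) > length(up) ||
                         (length(dn) == length(up) &&
                          sum(h$score[dn]) > sum(h$score[up]))) dn else up
        }
        if (length(chain) < kMin) next
        ch <- h[chain]
        cands[[length(cands) + 1L]] <- list(
            seqnames = as.character(GenomeInfoDb::seqnames(ch))[1],
            strand = if (sameStrand) as.character(BiocGenerics::strand(ch))[1]
                     else "*",
            start = min(BiocGenerics::start(ch)),
            end = max(BiocGenerics::end(ch)),
            matchedInOrder = length(chain),
            totalScore = sum(ch$score),
            hits = ch)
    }
    if (length(cands) == 0L) return(empty_candidates())
    gr <- GenomicRanges::GRanges(
        seqnames = vapply(cands, `[[`, character(1), "seqnames"),
        ranges = IRanges::IRanges(
            start = vapply(cands, `[[`, numeric(1), "start"),
            end = vapply(cands, `[[`, numeric(1), "end")),
        strand = vapply(cands, `[[`, character(1), "strand"))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        matchedInOrder = vapply(cands, `[[`, integer(1), "matchedInOrder"),
        totalScore = vapply(cands, `[[`, numeric(1), "totalScore"),
        hits = GenomicRanges::GRangesList(lapply(cands, `[[`, "hits")))
    gr[order(-gr$totalScore)]
}

empty_candidates <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        matchedInOrder = integer(0), totalScore = numeric(0),
        hits = GenomicRanges::GRangesList())
    gr
}

#' Chain block hits into a gene model
#'
#' Dynamic-programming chain over the hits of one scaffold and strand:
#' maximises total bit score minus `gapPenalty` per nucleotide of
#' inter-hit gap, subject to strict block-order collinearity and
#' non-overlap.  The stitched protein is the concatenation of the chained
#' hits' matched amino acids in block order.
#'
#' @param hits `GRanges` of block hits from one scaffold and strand (each
#'   block may contribute several alternatives).
#' @param gapPenalty Score cost per nt of gap between consecutive chained
#'   hits (default 0.001 bits/nt, mild enough that intron-scale gaps do
#'   not outweigh real hits).
#' @param nBlocks When given, a warning lists blocks absent from the
#'   chain (gapped model).
#' @param genome Optional `DNAStringSet`; when supplied the stitched
#'   mRNA (concatenated hit nucleotides, reverse-complemented on `-`)
#'   is returned too.
#' @return List with `chain` (`GRanges` in block order), `score`
#'   (chain objective), `protein` (stitched amino acids) and `mrna`
#'   (stitched nucleotides or `NA`).  Empty input gives an empty chain
#'   and a warning.
#' @export
chainGeneModel <- function(hits, gapPenalty = 0.001, nBlocks = NULL,
                           genome = NULL) {
    if (length(hits) == 0L) {
        warnf("no hits to chain: empty gene model")
        return(list(chain = empty_hits(), score = -Inf, protein = "",
                    mrna = NA_character_))
    }
    if (length(unique(as.character(GenomeInfoDb::seqnames(hits)))) != 1L ||
        length(unique(as.character(BiocGenerics::strand(hits)))) != 1L)
        stopf("chainGeneModel expects hits from one scaffold and strand")
    minus <- as.character(BiocGenerics::strand(hits))[1] == "-"
    s <- BiocGenerics::start(hits); e <- BiocGenerics::end(hits)
    # mirror reverse-strand coordinates so the chain always runs left-to-right
    if (minus) { tmp <- s; s <- -e; e <- -tmp }
    b <- hits$block; sc <- hits$score
    ord <- order(b, s)
    n <- length(hits)
    dp <- sc[ord]; prev <- rep(0L, n)
    for (i in seq_len(n)) {
        for (j in seq_len(i - 1L)) {
            if (b[ord[j]] < b[ord[i]] && e[ord[j]] < s[ord[i]]) {
                cand <- dp[j] + sc[ord[i]] -
                    gapPenalty * (s[ord[i]] - e[ord[j]] - 1L)
                if (cand > dp[i]) { dp[i] <- cand; prev[i] <- j }
            }
        }
    }
    best <- which.max(dp)
    chain <- integer(0); i <- best
    while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
    ch <- hits[ord[chain]]
    if (!is.null(nBlocks)) {
        missing_blocks <- setdiff(seq_len(nBlocks), ch$block)
        if (length(missing_blocks))
            warnf("gapped gene model: no chained hit for block(s) %s",
                  paste(missing_blocks, collapse = ", "))
    }
    mrna <- NA_character_
    if (!is.null(genome)) {
        pieces <- vapply(seq_along(ch), function(i) {
            nt <- Biostrings::subseq(
                genome[[as.character(GenomeInfoDb::seqnames(ch))[i]]],
                BiocGenerics::start(ch)[i], BiocGenerics::end(ch)[i])
            if (minus) nt <- Biostrings::reverseComplement(nt)
            as.character(nt)
        }, character(1))
        mrna <- paste(pieces, collapse = "")
    }
    list(chain = ch, score = dp[best],
         protein = paste(ch$aaSeq, collapse = ""), mrna = mrna)
}
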
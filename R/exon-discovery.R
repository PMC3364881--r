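#' Intronic regions between constant-exon anchors
#'
#' Given the anchor exons that flank each hypervariable cluster (for the
#' fly gene: the constant exons either side of the exon 4, 6 and 9
#' arrays), returns the intronic interval between each consecutive
#' anchor pair.  Anchors must be supplied in genomic order and must not
#' overlap; empty intervals between adjacent anchors are dropped.
#'
#' @param anchors `GRanges` of anchor exons with a metadata column
#'   `cluster` (e.g. `"Ig2"`, `"Ig3"`, `"Ig7"`); strand gives the host
#'   gene's strand.
#' @return `GRanges` of intronic regions carrying the `cluster` label and
#'   host strand.
#' @export
extractIntronicRegions <- function(anchors) {
    stopifnot(is(anchors, "GRanges"), !is.null(anchors$cluster))
    out <- list()
    key <- paste(GenomeInfoDb::seqnames(anchors), anchors$cluster)
    for (grp in split(seq_along(anchors), key)) {
        a <- anchors[grp]
        s <- BiocGenerics::start(a); e <- BiocGenerics::end(a)
        if (length(a) < 2L) next
        if (is.unsorted(s, strictly = TRUE))
            stopf("anchors for cluster '%s' out of order", a$cluster[1])
        if (any(e[-length(e)] >= s[-1]))
            stopf("anchors for cluster '%s' overlap", a$cluster[1])
        for (i in seq_len(length(a) - 1L)) {
            r0 <- e[i] + 1L; r1 <- s[i + 1L] - 1L
            if (r1 < r0) next
            out[[length(out) + 1L]] <- GenomicRanges::GRanges(
                seqnames = GenomeInfoDb::seqnames(a)[i],
                ranges = IRanges::IRanges(r0, r1),
                strand = BiocGenerics::strand(a)[i],
                cluster = a$cluster[i])
        }
    }
    if (length(out) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(cluster = character(0))
        return(gr)
    }
    suppressWarnings(do.call(c, out))
}

#' Scan intronic regions for hypervariable exon variants
#'
#' Each region is six-frame translated (both strands, so inverted exon
#' copies are found too) and every stop-free segment is scored against
#' the region's cluster HMM.  Hits passing the E-value cutoff are
#' resolved greedily by ascending E-value: a hit overlapping an already
#' kept hit by more than 50% of the shorter interval is discarded.  The
#' coding nucleotide sequence of each kept hit is retrieved
#' (reverse-complemented for hits on the reverse strand).
#'
#' @param clusterHMMs Named list of calibrated [ProfileHMM-class], one
#'   per cluster label appearing in `regions`.
#' @param regions `GRanges` from [extractIntronicRegions()] (metadata
#'   column `cluster`; strand = host gene strand).
#' @param genome `DNAStringSet` holding the scaffolds.
#' @param eCutoff E-value threshold (default 0.001).
#' @param geneticCode Genetic code for translation.
#' @return `GRanges` of exon-variant hits with metadata columns
#'   `cluster`, `frame`, `score`, `evalue`, `inverted` (hit strand
#'   opposite to host strand) and `ntSeq`.
#' @export
scanExonVariants <- function(clusterHMMs, regions, genome, eCutoff = 0.001,
                             geneticCode = Biostrings::GENETIC_CODE) {
    stopifnot(eCutoff > 0, is(genome, "DNAStringSet"),
              is(regions, "GRanges"))
    if (length(regions) == 0L) return(empty_variant_hits())
    missing_hmm <- setdiff(unique(regions$cluster), names(clusterHMMs))
    if (length(missing_hmm))
        stopf("no cluster HMM supplied for: %s",
              paste(missing_hmm, collapse = ", "))

    all_kept <- list()
    for (cl in unique(regions$cluster)) {
        hmm <- clusterHMMs[[cl]]
        if (!isCalibrated(hmm)) stopf("cluster HMM '%s' is not calibrated", cl)
        regs <- regions[regions$cluster == cl]
        seg_list <- lapply(seq_along(regs), function(i) {
            r <- regs[i]
            slice <- Biostrings::subseq(
                genome[[as.character(GenomeInfoDb::seqnames(r))]],
                BiocGenerics::start(r), BiocGenerics::end(r))
            segs <- sixFrameTranslate(slice, geneticCode = geneticCode,
                                      id = as.character(GenomeInfoDb::seqnames(r)))
            if (nrow(segs) == 0L) return(segs)
            segs$region <- i
            segs$nt_start <- segs$nt_start + BiocGenerics::start(r) - 1L
            segs$nt_end <- segs$nt_end + BiocGenerics::start(r) - 1L
            segs
        })
        segs <- do.call(rbind, seg_list)
        if (is.null(segs) || nrow(segs) == 0L) next
        dbSize <- nrow(segs)
        hits <- scan_hmm_segments(hmm, segs, eCutoff, dbSize,
                                  maxPerSegment = 10000L)
        if (is.null(hits)) next
        # region membership: hits live inside exactly one region interval
        hits$region <- vapply(seq_len(nrow(hits)), function(k) {
            w <- which(BiocGenerics::start(regs) - 1L <= hits$nt_start[k] &
                       BiocGenerics::end(regs) >= hits$nt_end[k] &
                       as.character(GenomeInfoDb::seqnames(regs)) ==
                           hits$seqnames[k])
            w[1]
        }, integer(1))
        for (ri in unique(hits$region)) {
            h <- hits[hits$region == ri, , drop = FALSE]
            kept <- resolve_overlaps(h)
            kept$cluster <- cl
            kept$hostStrand <-
                as.character(BiocGenerics::strand(regs))[ri]
            all_kept[[length(all_kept) + 1L]] <- kept
        }
    }
    if (length(all_kept) == 0L) return(empty_variant_hits())
    df <- do.call(rbind, all_kept)
    df$inverted <- df$strand != df$hostStrand
    df$ntSeq <- vapply(seq_len(nrow(df)), function(k) {
        nt <- Biostrings::subseq(genome[[df$seqnames[k]]],
                                 df$nt_start[k] + 1L, df$nt_end[k])
        if (df$strand[k] == "-") nt <- Biostrings::reverseComplement(nt)
        as.character(nt)
    }, character(1))
    df <- df[order(df$cluster, df$seqnames, df$nt_start), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
        seqnames = df$seqnames,
        ranges = IRanges::IRanges(df$nt_start + 1L, df$nt_end),
        strand = df$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        cluster = df$cluster, frame = as.integer(df$frame),
        score = df$score, evalue = df$evalue,
        inverted = df$inverted, ntSeq = df$ntSeq)
    gr
}

empty_variant_hits <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        cluster = character(0), frame = integer(0), score = numeric(0),
        evalue = numeric(0), inverted = logical(0), ntSeq = character(0))
    gr
}

# greedy overlap resolution: ascending E (ties: higher score, left-most),
# discard a hit overlapping a kept hit by > 50% of the shorter interval
resolve_overlaps <- function(h) {
    h <- h[order(h$evalue, -h$score, h$nt_start), , drop = FALSE]
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
        ok <- TRUE
        for (j in which(keep)) {
            ov <- min(h$nt_end[i], h$nt_end[j]) -
                  max(h$nt_start[i], h$nt_start[j])
            shorter <- min(h$nt_end[i] - h$nt_start[i],
                           h$nt_end[j] - h$nt_start[j])
            if (ov > 0.5 * shorter) { ok <- FALSE; break }
        }
        keep[i] <- ok
    }
    h[keep, , drop = FALSE]
}

#' Per-cluster exon-variant counts
#'
#' @param hits `GRanges` from [scanExonVariants()].
#' @param clusters Cluster labels to tabulate (default
#'   `c("Ig2", "Ig3", "Ig7")`); clusters without hits report 0.
#' @param genomeId Label for the genome column (default `"genome"`).
#' @return `data.frame` with columns `genome`, `cluster`, `n`.
#' @export
variantSummary <- function(hits, clusters = c("Ig2", "Ig3", "Ig7"),
                           genomeId = "genome") {
    n <- vapply(clusters, function(cl)
        if (length(hits) == 0L) 0L else sum(hits$cluster == cl), integer(1))
    data.frame(genome = genomeId, cluster = clusters, n = unname(n),
               row.names = NULL)
}
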
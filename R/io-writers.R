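# GFF3 emission goes through rtracklayer; all package coordinates are
# GRanges (1-based closed) so the 0-based half-open conversion happens once,
# at TSV boundaries.

#' Write block hits as a tab-separated table
#'
#' Columns: `scaffold`, `block`, `strand`, `frame`, `nt_start`, `nt_end`
#' (0-based half-open), `score`, `evalue`, `aa_seq`.  [readHitsTSV()]
#' restores the equivalent `GRanges`.
#'
#' @param hits `GRanges` from [scanGenome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeHitsTSV <- function(hits, path) {
    df <- data.frame(
        scaffold = as.character(GenomeInfoDb::seqnames(hits)),
        block = hits$block,
        strand = as.character(BiocGenerics::strand(hits)),
        frame = hits$frame,
        nt_start = BiocGenerics::start(hits) - 1L,
        nt_end = BiocGenerics::end(hits),
        score = sprintf("%.17g", hits$score),
        evalue = sprintf("%.17g", hits$evalue),
        aa_seq = hits$aaSeq)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a hits table written by [writeHitsTSV()]
#'
#' @param path Input file.
#' @return `GRanges` with the same metadata columns as [scanGenome()]
#'   output.
#' @export
readHitsTSV <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c(scaffold = "character",
                                    aa_seq = "character"))
    if (nrow(df) == 0L) return(empty_hits())
    hits_df_to_granges(data.frame(
        seqnames = df$scaffold, strand = df$strand, frame = df$frame,
        nt_start = df$nt_start, nt_end = df$nt_end,
        score = as.numeric(df$score), evalue = as.numeric(df$evalue),
        aaSeq = df$aa_seq, block = df$block))
}

gff3_granges <- function(gr, type, source = "dscamtools", ID = NULL,
                         Parent = NULL, extra = list()) {
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                  IRanges::ranges(gr),
                                  BiocGenerics::strand(gr))
    md <- S4Vectors::DataFrame(source = rep(source, length(gr)),
                               type = rep(type, length.out = length(gr)))
    if (!is.null(ID)) md$ID <- ID
    if (!is.null(Parent)) md$Parent <- Parent
    for (nm in names(extra)) md[[nm]] <- extra[[nm]]
    S4Vectors::mcols(out) <- md
    out
}

#' Write block hits as GFF3 `protein_match` features
#'
#' @param hits `GRanges` from [scanGenome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeHitsGFF3 <- function(hits, path) {
    gr <- gff3_granges(hits, "protein_match",
        ID = sprintf("hit%d", seq_along(hits)),
        extra = list(block = hits$block, frame = hits$frame,
                     bitscore = hits$score, evalue = hits$evalue))
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Write gene candidates as GFF3 gene features with child matches
#'
#' Each candidate becomes a `gene` feature spanning its block hits, with
#' one `protein_match` child per chained hit.
#'
#' @param cands `GRanges` from [callCandidates()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeCandidatesGFF3 <- function(cands, path) {
    if (length(cands) == 0L) {
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    genes <- gff3_granges(cands, "gene",
        ID = sprintf("candidate%d", seq_along(cands)),
        extra = list(matchedInOrder = cands$matchedInOrder,
                     bitscore = cands$totalScore))
    kids <- list()
    for (i in seq_along(cands)) {
        h <- cands$hits[[i]]
        kids[[i]] <- gff3_granges(h, "protein_match",
            ID = sprintf("candidate%d.block%d", i, h$block),
            Parent = rep(sprintf("candidate%d", i), length(h)),
            extra = list(block = h$block, frame = h$frame,
                         bitscore = h$score, evalue = h$evalue))
    }
    all <- suppressWarnings(c(genes, do.call(c, kids)))
    rtracklayer::export(all, path, format = "gff3")
    invisible(path)
}

#' Write synthetic truth annotations as GFF3
#'
#' @param truth Truth `GRanges` from the planting functions.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTruthGFF3 <- function(truth, path) {
    if (length(truth) == 0L) {
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    gr <- gff3_granges(truth, truth$type, source = "synthetic",
        ID = truth$featureId,
        extra = list(source_id = truth$source, cluster = truth$cluster,
                     mutations = truth$mutations))
    parent <- truth$parent
    has_parent <- !is.na(parent)
    md <- S4Vectors::mcols(gr)
    md$Parent <- ifelse(has_parent, parent, NA_character_)
    S4Vectors::mcols(gr) <- md
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Write exon-variant hits as GFF3 and FASTA
#'
#' @param variants `GRanges` from [scanExonVariants()].
#' @param gff3Path,fastaPath Output files (`NULL` to skip either).
#' @return Invisibly, a list of the written paths.
#' @export
writeVariants <- function(variants, gff3Path = NULL, fastaPath = NULL) {
    ids <- if (length(variants))
        sprintf("%s_var%d", variants$cluster, seq_along(variants))
    else character(0)
    if (!is.null(gff3Path)) {
        if (length(variants) == 0L) writeLines("##gff-version 3", gff3Path)
        else {
            gr <- gff3_granges(variants, "exon", ID = ids,
                extra = list(cluster = variants$cluster,
                             frame = variants$frame,
                             bitscore = variants$score,
                             evalue = variants$evalue,
                             inverted = variants$inverted))
            rtracklayer::export(gr, gff3Path, format = "gff3")
        }
    }
    if (!is.null(fastaPath)) {
        seqs <- Biostrings::DNAStringSet(
            if (length(variants)) variants$ntSeq else character(0))
        names(seqs) <- ids
        Biostrings::writeXStringSet(seqs, fastaPath)
    }
    invisible(list(gff3 = gff3Path, fasta = fastaPath))
}

#' Read scan regions from a BED file
#'
#' BED intervals (0-based half-open on disk) become 1-based `GRanges`;
#' the BED name column supplies the cluster label.
#'
#' @param path BED file.
#' @return `GRanges` with a `cluster` metadata column.
#' @export
readRegionsBED <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    cl <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(cluster = cl)
    gr
}
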
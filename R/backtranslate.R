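#' Codon-aware back-translation of a protein alignment
#'
#' Replaces every residue column of a protein alignment by the source
#' codon from the matching coding sequence and every gap by `---`,
#' producing a codon alignment of exactly three times the protein
#' alignment width (the step that prepares exon alignments for
#' nucleotide-level phylogenetics).  Each CDS must translate exactly to
#' its ungapped protein under the standard genetic code; a trailing stop
#' codon on the CDS is tolerated and dropped.
#'
#' @param proteinAln `AAStringSet` (aligned, with `-` gaps) or an
#'   [AnnotatedAlignment-class].
#' @param cds Named `DNAStringSet` or named character vector of coding
#'   sequences covering every alignment id.
#' @return `DNAStringSet` codon alignment with the same names.
#' @export
#' @examples
#' aln <- Biostrings::AAStringSet(c(s1 = "M-K", s2 = "MEK"))
#' cds <- c(s1 = "ATGAAA", s2 = "ATGGAGAAG")
#' as.character(backTranslate(aln, cds))
backTranslate <- function(proteinAln, cds) {
    if (is(proteinAln, "AnnotatedAlignment"))
        proteinAln <- proteinAln@sequences
    if (is.character(proteinAln))
        proteinAln <- Biostrings::AAStringSet(proteinAln)
    if (is(cds, "DNAStringSet")) cds <- as.character(cds)
    ids <- names(proteinAln)
    if (is.null(ids)) stopf("protein alignment sequences must be named")
    missing_cds <- setdiff(ids, names(cds))
    if (length(missing_cds))
        stopf("missing CDS for: %s", paste(missing_cds, collapse = ", "))

    out <- vapply(ids, function(id) {
        aa <- strsplit(as.character(proteinAln[[id]]), "")[[1]]
        ung <- aa[aa != "-"]
        nt <- toupper(cds[[id]])
        n_codon <- nchar(nt) %/% 3L
        if (nchar(nt) %% 3L != 0L)
            stopf("CDS for '%s' length %d is not a multiple of 3", id, nchar(nt))
        codons <- substring(nt, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
        if (n_codon == length(ung) + 1L &&
            codons[n_codon] %in% c("TAA", "TAG", "TGA")) {
            codons <- codons[-n_codon]; n_codon <- n_codon - 1L
        }
        if (n_codon != length(ung))
            stopf("CDS for '%s' encodes %d residues but protein has %d",
                  id, n_codon, length(ung))
        trans <- as.character(Biostrings::translate(
            Biostrings::DNAString(paste(codons, collapse = "")),
            no.init.codon = TRUE))
        mism <- which(strsplit(trans, "")[[1]] != ung)
        if (length(mism))
            stopf("CDS for '%s' translates to '%s' but protein has '%s' at position %d",
                  id, substring(trans, mism[1], mism[1]), ung[mism[1]], mism[1])
        res <- character(length(aa))
        res[aa == "-"] <- "---"
        res[aa != "-"] <- codons
        paste(res, collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(setNames(out, ids))
}

#' Size of the mutually exclusive splicing isoform space
#'
#' With one variant chosen from each mutually exclusive cluster and each
#' optional exon independently present or absent, the number of distinct
#' transcripts is
#' \deqn{\prod_i \text{sizes}_i \times 2^{n_{optional}}.}
#' For the fly hypervariable gene, clusters of 12, 48, 33 and 2 variants
#' give 38,016 transcripts, and the two optional endodomain exons raise
#' this to 152,064.
#'
#' @param sizes Positive integer vector, one entry per cluster.
#' @param nOptional Count of independently optional exons (default 0).
#' @return Exact integer count (as numeric; an error is raised beyond
#'   exact double range).
#' @export
#' @examples
#' isoformSpace(c(12, 48, 33, 2))       # 38016
#' isoformSpace(c(12, 48, 33, 2), 2)    # 152064
isoformSpace <- function(sizes, nOptional = 0L) {
    if (length(sizes) == 0L || any(sizes < 1L) || any(sizes != floor(sizes)))
        stopf("sizes must be positive integers")
    if (nOptional < 0L || nOptional != floor(nOptional))
        stopf("nOptional must be a non-negative integer")
    total <- prod(as.numeric(sizes)) * 2^as.numeric(nOptional)
    if (total > 2^53)
        stopf("isoform count exceeds exact integer range")
    total
}
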
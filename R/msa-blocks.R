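#' Read a protein alignment with exon-boundary annotations
#'
#' Reads a multiple protein alignment (FASTA or Stockholm) and an optional
#' boundary table, returning a validated [AnnotatedAlignment-class].  The
#' boundary table is tab-separated with two columns: sequence id and a
#' comma-separated list of integer exon boundaries in ungapped residue
#' coordinates (each value counts the residues preceding the boundary).
#' Sequences without a row get an empty boundary list.
#'
#' @param alignmentFile Path to the alignment (FASTA or Stockholm; `.`
#'   gap characters are normalised to `-`).
#' @param boundaryFile Optional path to the boundary table.
#' @param format `"auto"` (sniff the first line), `"fasta"` or
#'   `"stockholm"`.
#' @return An [AnnotatedAlignment-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">seq1", "ACDEF", ">seq2", "ACDEF"), f)
#' b <- tempfile()
#' writeLines("seq1\t2", b)
#' readAnnotatedAlignment(f, b)
readAnnotatedAlignment <- function(alignmentFile, boundaryFile = NULL,
                                   format = c("auto", "fasta", "stockholm")) {
    format <- match.arg(format)
    if (format == "auto") {
        first <- readLines(alignmentFile, n = 1L)
        format <- if (grepl("^#\\s*STOCKHOLM", first)) "stockholm" else "fasta"
    }
    aln <- tryCatch(
        Biostrings::readAAMultipleAlignment(alignmentFile, format = format),
        error = function(e) stopf("alignment format error in '%s': %s",
                                  alignmentFile, conditionMessage(e)))
    seqs <- as(aln, "AAStringSet")
    seqs <- Biostrings::AAStringSet(toupper(gsub(".", "-",
        as.character(seqs), fixed = TRUE)))
    boundaries <- list()
    if (!is.null(boundaryFile)) {
        tab <- read.table(boundaryFile, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("id", "bounds"), fill = TRUE)
        for (i in seq_len(nrow(tab))) {
            id <- tab$id[i]
            if (!id %in% names(seqs))
                stopf("boundary table id '%s' not in alignment", id)
            bs <- tab$bounds[i]
            boundaries[[id]] <- if (nzchar(bs))
                as.integer(strsplit(bs, ",")[[1]]) else integer(0)
        }
    }
    new("AnnotatedAlignment", sequences = seqs, boundaries = boundaries)
}

# cumulative non-gap residue counts: row per sequence, col j = residues in
# columns 1..j (col index offset by 1; [, 1] is 0)
ungapped_prefix <- function(aln) {
    chars <- vapply(as.character(aln@sequences), function(s)
        strsplit(s, "")[[1]] != "-", logical(Biostrings::width(aln@sequences)[1]))
    apply(rbind(FALSE, chars), 2, cumsum)  # (W+1) x nseq
}

# TRUE when the column window [start, start+len-1] crosses an exon boundary
# of any member sequence
window_crosses_boundary <- function(prefix, boundaries, ids, start, len) {
    for (k in seq_along(ids)) {
        b <- boundaries[[ids[k]]]
        if (is.null(b) || length(b) == 0L) next
        u0 <- prefix[start, k]
        u1 <- prefix[start + len, k]
        if (any(b > u0 & b < u1)) return(TRUE)
    }
    FALSE
}

#' Extract ordered conserved blocks from an annotated alignment
#'
#' Finds up to `nBlocks` non-overlapping alignment windows, each of length
#' between `minLen` and `maxLen` columns, that (i) cross no member
#' sequence's exon boundary and (ii) maximise a conservation score: the
#' mean over window columns of the majority-residue fraction (gap
#' characters score 0).  Selection is greedy by descending score with
#' ties broken by leftmost start, then longer window; chosen windows
#' exclude overlapping later candidates.  The result is returned sorted
#' by column position and indexed 1..k in that order, encoding the
#' expected genomic order of the homologous regions.
#'
#' @param aln An [AnnotatedAlignment-class].
#' @param nBlocks Maximum number of blocks to return.
#' @param minLen,maxLen Window length bounds in alignment columns.
#' @return List of [BlockDefinition-class], sorted by `colStart`.  If
#'   fewer than `nBlocks` boundary-free windows exist a warning is issued
#'   and the shorter list returned.
#' @export
extractBlocks <- function(aln, nBlocks, minLen, maxLen = minLen) {
    stopifnot(is(aln, "AnnotatedAlignment"))
    W <- Biostrings::width(aln@sequences)[1]
    if (nBlocks == 0L) return(list())
    if (!(nBlocks >= 1L && minLen >= 1L && minLen <= maxLen && maxLen <= W))
        stopf("require 1 <= minLen <= maxLen <= alignment width and nBlocks >= 1")

    mat <- do.call(rbind, strsplit(as.character(aln@sequences), ""))
    nseq <- nrow(mat)
    colscore <- vapply(seq_len(W), function(j) {
        col <- mat[, j]
        res <- col[col != "-"]
        if (length(res) == 0L) return(0)
        max(table(res)) / nseq
    }, numeric(1))
    csum <- c(0, cumsum(colscore))
    prefix <- ungapped_prefix(aln)
    ids <- names(aln@sequences)

    cand <- list()
    for (len in seq(minLen, maxLen)) {
        for (start in seq_len(W - len + 1L)) {
            if (window_crosses_boundary(prefix, aln@boundaries, ids, start, len))
                next
            cand[[length(cand) + 1L]] <- c(start = start, len = len,
                score = (csum[start + len] - csum[start]) / len)
        }
    }
    if (length(cand) == 0L) {
        warnf("no boundary-free window of length >= %d exists; returning 0 blocks",
              minLen)
        return(list())
    }
    cm <- do.call(rbind, cand)
    ord <- order(-cm[, "score"], cm[, "start"], -cm[, "len"])
    cm <- cm[ord, , drop = FALSE]

    chosen <- matrix(numeric(0), ncol = 3,
                     dimnames = list(NULL, c("start", "len", "score")))
    for (i in seq_len(nrow(cm))) {
        if (nrow(chosen) >= nBlocks) break
        s <- cm[i, "start"]; l <- cm[i, "len"]
        if (nrow(chosen) > 0 &&
            any(s < chosen[, "start"] + chosen[, "len"] &
                chosen[, "start"] < s + l)) next
        chosen <- rbind(chosen, cm[i, ])
    }
    if (nrow(chosen) < nBlocks)
        warnf("only %d non-overlapping boundary-free blocks found (%d requested)",
              nrow(chosen), nBlocks)

    chosen <- chosen[order(chosen[, "start"]), , drop = FALSE]
    lapply(seq_len(nrow(chosen)), function(i) {
        s <- as.integer(chosen[i, "start"]); l <- as.integer(chosen[i, "len"])
        sub <- sliceAlignment(aln, s, s + l - 1L)
        new("BlockDefinition", index = i, colStart = s,
            colEnd = s + l - 1L, alignment = sub,
            score = unname(chosen[i, "score"]))
    })
}

#' Slice an annotated alignment by columns
#'
#' Takes alignment columns `colStart..colEnd` (1-based closed) and remaps
#' each sequence's exon boundaries into the slice's ungapped coordinates,
#' keeping only boundaries that fall strictly inside the slice.
#'
#' @param aln An [AnnotatedAlignment-class].
#' @param colStart,colEnd Column interval, 1-based closed.
#' @return An [AnnotatedAlignment-class] over the selected columns.
#' @export
sliceAlignment <- function(aln, colStart, colEnd) {
    seqs <- Biostrings::subseq(aln@sequences, colStart, colEnd)
    prefix <- ungapped_prefix(aln)
    ids <- names(aln@sequences)
    boundaries <- list()
    for (k in seq_along(ids)) {
        b <- aln@boundaries[[ids[k]]]
        if (is.null(b) || length(b) == 0L) next
        u0 <- prefix[colStart, k]; u1 <- prefix[colEnd + 1L, k]
        keep <- b[b > u0 & b < u1] - u0
        if (length(keep)) boundaries[[ids[k]]] <- as.integer(keep)
    }
    new("AnnotatedAlignment", sequences = seqs, boundaries = boundaries)
}

#' Pick one representative leaf per clade of a tree
#'
#' Cuts a rooted, branch-length-annotated tree at root distance
#' `treeHeight - height` (tree height = maximum root-to-leaf distance).
#' Each subtree hanging below the cut is a cluster; leaves shallower than
#' the cut form singleton clusters.  Within each cluster the medoid leaf
#' is returned: the leaf with the smallest mean patristic distance to the
#' other cluster members, ties broken by lexicographic id.
#'
#' @param tree A Newick string, a file path, or an [ape::read.tree] `phylo`
#'   object.  Must be rooted with branch lengths.
#' @param height Non-negative branch-length threshold; `0` returns every
#'   leaf, values above the tree height return a single leaf.
#' @return Character vector of leaf ids, sorted.
#' @export
selectRepresentatives <- function(tree, height) {
    if (is.character(tree)) {
        tree <- suppressWarnings(
            if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree))
        if (is.null(tree)) stopf("could not parse Newick input")
    }
    if (!inherits(tree, "phylo")) stopf("tree must be phylo or Newick")
    if (is.null(tree$edge.length)) stopf("tree must have branch lengths")
    if (!ape::is.rooted(tree)) stopf("tree must be rooted")
    if (height < 0) stopf("height must be >= 0")

    ntip <- length(tree$tip.label)
    depth <- ape::node.depth.edgelength(tree)
    H <- max(depth[seq_len(ntip)])
    cutDepth <- H - height

    parent <- integer(ntip + tree$Nnode)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    root <- ntip + 1L

    cluster <- integer(ntip)
    for (tip in seq_len(ntip)) {
        path <- tip
        node <- tip
        while (node != root) { node <- parent[node]; path <- c(node, path) }
        hit <- path[depth[path] > cutDepth]
        cluster[tip] <- if (length(hit)) hit[1] else tip
    }

    pat <- ape::cophenetic.phylo(tree)
    reps <- vapply(split(seq_len(ntip), cluster), function(members) {
        labs <- tree$tip.label[members]
        if (length(labs) == 1L) return(labs)
        msd <- vapply(labs, function(l) mean(pat[l, setdiff(labs, l)]), numeric(1))
        best <- labs[msd == min(msd)]
        sort(best)[1]
    }, character(1))
    sort(unname(reps))
}

#' Serialize block definitions to JSON
#'
#' Writes block index, column interval and member sequence ids; the
#' companion [readBlocksJSON()] restores the same table.
#'
#' @param blocks List of [BlockDefinition-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeBlocksJSON <- function(blocks, path) {
    rec <- lapply(blocks, function(b) list(
        index = b@index, colStart = b@colStart, colEnd = b@colEnd,
        score = b@score, members = names(b@alignment@sequences)))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read block definitions written by [writeBlocksJSON()]
#'
#' @param path JSON file.
#' @return `data.frame` with columns `index`, `colStart`, `colEnd`,
#'   `score` and a list-column `members`.
#' @export
readBlocksJSON <- function(path) {
    rec <- jsonlite::read_json(path)
    data.frame(
        index = vapply(rec, function(r) as.integer(r$index), integer(1)),
        colStart = vapply(rec, function(r) as.integer(r$colStart), integer(1)),
        colEnd = vapply(rec, function(r) as.integer(r$colEnd), integer(1)),
        score = vapply(rec, function(r) as.numeric(r$score), numeric(1)),
        members = I(lapply(rec, function(r) unlist(r$members))))
}
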
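#' Seeded random genome
#'
#' Generates `nScaffolds` scaffolds of i.i.d. nucleotides with
#' `P(G or C) = gc` (split evenly between G and C, likewise A/T).
#' Identical `(spec, seed)` give byte-identical output — the
#' negative-control genome of the scanning benchmark.
#'
#' @param nScaffolds Number of scaffolds (>= 1).
#' @param scaffoldLen Length of each scaffold in nt (>= 3).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param seed Integer seed.
#' @param prefix Scaffold name prefix.
#' @return List with `genome` (`DNAStringSet`) and `truth` (empty
#'   `GRanges`).
#' @export
#' @examples
#' g <- randomGenome(2, 100, seed = 1)
#' identical(as.character(g$genome), as.character(randomGenome(2, 100, seed = 1)$genome))
randomGenome <- function(nScaffolds, scaffoldLen, gc = 0.5, seed = 1L,
                         prefix = "scaffold") {
    if (nScaffolds < 1L || scaffoldLen < 3L || gc < 0 || gc > 1)
        stopf("invalid genome spec: need nScaffolds >= 1, scaffoldLen >= 3, gc in [0,1]")
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bytes <- charToRaw("ACGT")
    seqs <- with_seed(seed, {
        vapply(seq_len(nScaffolds), function(i)
            rawToChar(bytes[sample.int(4L, scaffoldLen, replace = TRUE,
                                       prob = p)]),
            character(1))
    })
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("%s%d", prefix, seq_len(nScaffolds))
    list(genome = genome, truth = empty_truth())
}

empty_truth <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        type = character(0), featureId = character(0),
        parent = character(0), source = character(0),
        cluster = character(0), exonIndex = integer(0),
        mutations = integer(0))
    gr
}

truth_row <- function(seqnames, start, end, strand, type, featureId,
                      parent = NA_character_, source = NA_character_,
                      cluster = NA_character_, exonIndex = NA_integer_,
                      mutations = NA_integer_) {
    gr <- GenomicRanges::GRanges(seqnames, IRanges::IRanges(start, end),
                                 strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        type = type, featureId = featureId, parent = parent,
        source = source, cluster = cluster,
        exonIndex = as.integer(exonIndex), mutations = as.integer(mutations))
    gr
}

# synonymous codon lists for uniform reverse translation
codon_table <- function(geneticCode = Biostrings::GENETIC_CODE) {
    split(names(geneticCode), geneticCode)
}

# seeded uniform-synonymous-codon reverse translation (RNG state is the
# caller's responsibility)
reverse_translate <- function(protein, codons) {
    aa <- strsplit(protein, "")[[1]]
    paste(vapply(aa, function(a) {
        opts <- codons[[a]]
        if (is.null(opts)) stopf("cannot reverse-translate residue '%s'", a)
        opts[sample.int(length(opts), 1L)]
    }, character(1)), collapse = "")
}

# Per-nt substitutions at `rate`, uniform over the 3 alternatives.  One
# uniform and one alternative-choice draw are consumed per position whether
# or not it mutates, so sweeps over `rate` under a fixed seed are nested:
# the mutations at a lower rate are a subset of those at a higher rate.
mutate_nt <- function(seq, rate) {
    chars <- strsplit(seq, "")[[1]]
    if (rate <= 0) return(list(seq = seq, count = 0L))
    u <- runif(length(chars))
    pick <- sample.int(3L, length(chars), replace = TRUE)
    hit <- which(u < rate)
    for (i in hit)
        chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[pick[i]]
    list(seq = paste(chars, collapse = ""), count = length(hit))
}

contains_stop_in_frame <- function(seq) {
    n <- nchar(seq) %/% 3L
    if (n == 0L) return(FALSE)
    codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    any(codons %in% c("TAA", "TAG", "TGA"))
}

check_placement <- function(truth, scaffold, start, end) {
    if (length(truth) == 0L) return(invisible(TRUE))
    spans <- truth[truth$type %in% c("gene", "array")]
    same <- spans[as.character(GenomeInfoDb::seqnames(spans)) == scaffold]
    if (any(BiocGenerics::start(same) <= end & BiocGenerics::end(same) >= start))
        stopf("planted feature [%d, %d] on '%s' overlaps an existing feature",
              start, end, scaffold)
    invisible(TRUE)
}

#' Plant a multi-exon gene into a genome
#'
#' Reverse-translates a source protein with uniform synonymous codon
#' choice, splits it into exons per the exon plan, inserts introns that
#' begin `GT`, end `AG` and carry an in-frame stop codon within their
#' first 9 nt (so no block HMM match can run through an intron), applies
#' per-nt substitutions at the given rate, and overwrites the target
#' scaffold region.  Truth records the exact exon intervals and the
#' realised substitution count.
#'
#' @param genome `DNAStringSet`.
#' @param plant List with elements `protein` (amino-acid string),
#'   `exonPlan` (exon lengths in aa, summing to the protein length),
#'   `intronLens` (nt, one fewer than exons, each >= 10), `mutationRate`
#'   (per-nt substitution probability in `[0, 1)`), `scaffold` (name),
#'   `offset` (0-based nt), `strand` (`"+"`/`"-"`), optional `id` and
#'   `source`.
#' @param seed Integer seed.
#' @param truth Existing truth `GRanges`; placement overlapping a
#'   recorded gene/array span is an error.
#' @return List with modified `genome` and extended `truth`.
#' @export
plantGene <- function(genome, plant, seed = 1L, truth = empty_truth()) {
    p <- plant
    stopifnot(sum(p$exonPlan) == nchar(p$protein),
              length(p$intronLens) == length(p$exonPlan) - 1L,
              p$mutationRate >= 0, p$mutationRate < 1)
    if (any(p$intronLens < 10L)) stopf("intron lengths must be >= 10 nt")
    id <- if (!is.null(p$id)) p$id else "gene1"
    src <- if (!is.null(p$source)) p$source else "sourceProtein"
    strand <- if (!is.null(p$strand)) p$strand else "+"
    scaffold <- p$scaffold
    if (!scaffold %in% names(genome)) stopf("scaffold '%s' not in genome", scaffold)

    built <- with_seed(seed, {
        codons <- codon_table()
        cds <- reverse_translate(p$protein, codons)
        exon_nt <- 3L * p$exonPlan
        exon_ends <- cumsum(exon_nt)
        exon_starts <- c(1L, head(exon_ends, -1L) + 1L)
        exons <- substring(cds, exon_starts, exon_ends)
        introns <- vapply(p$intronLens, function(len) {
            stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
            mid <- paste(sample(c("A", "C", "G", "T"), len - 8L,
                                replace = TRUE), collapse = "")
            paste0("GT", sample(c("A", "C", "G", "T"), 1L), stop_codon,
                   mid, "AG")
        }, character(1))
        pieces <- character(0)
        for (i in seq_along(exons)) {
            pieces <- c(pieces, exons[i])
            if (i < length(exons)) pieces <- c(pieces, introns[i])
        }
        construct <- paste(pieces, collapse = "")
        mut <- mutate_nt(construct, p$mutationRate)
        list(construct = mut$seq, nmut = mut$count,
             exon_nt = exon_nt, intron_nt = nchar(introns))
    })
    total <- nchar(built$construct)
    scaf_len <- Biostrings::width(genome)[names(genome) == scaffold]
    if (p$offset < 0L || p$offset + total > scaf_len)
        stopf("plant does not fit: needs [%d, %d) on '%s' (length %d)",
              p$offset, p$offset + total, scaffold, scaf_len)
    check_placement(truth, scaffold, p$offset + 1L, p$offset + total)

    final <- if (strand == "-")
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(built$construct)))
    else built$construct
    seqs <- as.character(genome)
    s <- seqs[[scaffold]]
    seqs[[scaffold]] <- paste0(substring(s, 1L, p$offset), final,
                               substring(s, p$offset + total + 1L))
    genome2 <- Biostrings::DNAStringSet(seqs)

    # biological-order exon nt intervals within the construct (0-based)
    b0 <- integer(0); b1 <- integer(0); pos <- 0L
    for (i in seq_along(built$exon_nt)) {
        b0 <- c(b0, pos); b1 <- c(b1, pos + built$exon_nt[i])
        pos <- pos + built$exon_nt[i]
        if (i < length(built$exon_nt)) pos <- pos + built$intron_nt[i]
    }
    if (strand == "-") {
        f0 <- p$offset + total - b1; f1 <- p$offset + total - b0
    } else {
        f0 <- p$offset + b0; f1 <- p$offset + b1
    }
    rows <- truth_row(scaffold, p$offset + 1L, p$offset + total, strand,
                      "gene", id, source = src, mutations = built$nmut)
    for (i in seq_along(f0))
        rows <- suppressWarnings(c(rows, truth_row(scaffold, f0[i] + 1L, f1[i], strand,
                                  "exon", sprintf("%s.exon%d", id, i),
                                  parent = id, source = src, exonIndex = i)))
    list(genome = genome2, truth = suppressWarnings(c(truth, rows)))
}

#' Plant a tandem array of diverged exon variants
#'
#' Emulates a mutually exclusive splicing cluster: `nVariants` copies of
#' a base exon, each independently mutated per-nt at the divergence
#' rate (substitutions that would introduce an in-frame stop codon are
#' resampled), separated by random spacers, written onto the target
#' scaffold.
#'
#' @param genome `DNAStringSet`.
#' @param baseExon In-frame, stop-free nucleotide string (length a
#'   multiple of 3).
#' @param nVariants Number of copies.
#' @param divergence Per-nt substitution rate in `[0, 1)`.
#' @param spacerLen Random spacer length between copies (nt).
#' @param scaffold,offset Target scaffold name and 0-based offset.
#' @param strand Strand the variants are written on (default `"+"`).
#' @param cluster Cluster label recorded in truth (default `"Ig2"`).
#' @param seed Integer seed.
#' @param truth Existing truth `GRanges` (placement checked).
#' @param id Array feature id.
#' @return List with modified `genome` and extended `truth` (one
#'   `variant` row per copy plus an `array` span row).
#' @export
plantExonArray <- function(genome, baseExon, nVariants, divergence,
                           spacerLen, scaffold, offset, strand = "+",
                           cluster = "Ig2", seed = 1L,
                           truth = empty_truth(), id = NULL) {
    stopifnot(nVariants >= 1L, divergence >= 0, divergence < 1,
              nchar(baseExon) %% 3L == 0L)
    if (contains_stop_in_frame(baseExon))
        stopf("baseExon must be stop-free in frame 0")
    if (is.null(id)) id <- paste0("array_", cluster)
    exon_len <- nchar(baseExon)

    built <- with_seed(seed, {
        variants <- vapply(seq_len(nVariants), function(i) {
            repeat {
                m <- mutate_nt(baseExon, divergence)
                if (!contains_stop_in_frame(m$seq)) return(m$seq)
            }
        }, character(1))
        spacers <- vapply(seq_len(nVariants - 1L), function(i)
            paste(sample(c("A", "C", "G", "T"), spacerLen, replace = TRUE),
                  collapse = ""), character(1))
        pieces <- character(0)
        for (i in seq_len(nVariants)) {
            pieces <- c(pieces, variants[i])
            if (i < nVariants) pieces <- c(pieces, spacers[i])
        }
        paste(pieces, collapse = "")
    })
    total <- nchar(built)
    scaf_len <- Biostrings::width(genome)[names(genome) == scaffold]
    if (offset < 0L || offset + total > scaf_len)
        stopf("array does not fit on scaffold '%s'", scaffold)
    check_placement(truth, scaffold, offset + 1L, offset + total)

    final <- if (strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(built)))
    else built
    seqs <- as.character(genome)
    s <- seqs[[scaffold]]
    seqs[[scaffold]] <- paste0(substring(s, 1L, offset), final,
                               substring(s, offset + total + 1L))
    genome2 <- Biostrings::DNAStringSet(seqs)

    step <- exon_len + spacerLen
    v0 <- offset + (seq_len(nVariants) - 1L) * step
    if (strand == "-") {
        tmp <- offset + total - (v0 - offset) - exon_len
        v0 <- rev(tmp)
    }
    rows <- truth_row(scaffold, offset + 1L, offset + total, strand,
                      "array", id, cluster = cluster)
    for (i in seq_len(nVariants))
        rows <- suppressWarnings(c(rows, truth_row(scaffold, v0[i] + 1L, v0[i] + exon_len,
                                  strand, "variant",
                                  sprintf("%s.v%d", id, i), parent = id,
                                  cluster = cluster)))
    list(genome = genome2, truth = suppressWarnings(c(truth, rows)))
}

#' Synthetic protein family for block-HMM training
#'
#' Draws an ancestor protein from the background composition and derives
#' family members by independent per-site substitution, yielding an
#' ungapped alignment with identical exon boundaries across members —
#' the statistical shape the block extractor and profile builder assume.
#'
#' @param seed Integer seed.
#' @param nSeqs Family size (default 5).
#' @param nExons Exons per gene (default 10).
#' @param exonLenAA Exon length in residues (default 60).
#' @param divergence Per-site substitution probability from the ancestor
#'   (default 0.15).
#' @return List with `alignment` ([AnnotatedAlignment-class] including
#'   the ancestor as `ancestor`), `ancestor` (protein string) and
#'   `exonPlan`.
#' @export
syntheticFamily <- function(seed = 1L, nSeqs = 5L, nExons = 10L,
                            exonLenAA = 60L, divergence = 0.15) {
    stopifnot(nSeqs >= 2L, nExons >= 1L, exonLenAA >= 1L)
    bg <- robinsonBackground()
    len <- nExons * exonLenAA
    out <- with_seed(seed, {
        anc <- sample(AA_ALPHABET, len, replace = TRUE, prob = bg)
        members <- vapply(seq_len(nSeqs), function(i) {
            m <- anc
            hit <- which(runif(len) < divergence)
            for (k in hit)
                m[k] <- sample(setdiff(AA_ALPHABET, m[k]), 1L,
                               prob = bg[setdiff(AA_ALPHABET, m[k])])
            paste(m, collapse = "")
        }, character(1))
        list(anc = paste(anc, collapse = ""), members = members)
    })
    ids <- c("ancestor", sprintf("member%d", seq_len(nSeqs)))
    seqs <- Biostrings::AAStringSet(c(out$anc, out$members))
    names(seqs) <- ids
    bounds <- cumsum(rep(exonLenAA, nExons))
    bounds <- bounds[-length(bounds)]
    boundaries <- setNames(rep(list(as.integer(bounds)), length(ids)), ids)
    aln <- new("AnnotatedAlignment", sequences = seqs,
               boundaries = boundaries)
    list(alignment = aln, ancestor = out$anc,
         exonPlan = rep(exonLenAA, nExons))
}

#' Representative training set for an exon-cluster HMM
#'
#' Derives `nReps` diverged copies of a base exon (per-nt substitution at
#' the given rate, in-frame stops resampled), translates them, and
#' returns the resulting ungapped protein alignment — the
#' one-representative-per-clade training set used to build a cluster HMM
#' without over-representing closely related variants.
#'
#' @param baseExon In-frame, stop-free nucleotide string (length a
#'   multiple of 3).
#' @param nReps Number of representatives (>= 2; default 3).
#' @param divergence Per-nt substitution rate (default 0.1).
#' @param seed Integer seed.
#' @return An [AnnotatedAlignment-class] of the translated
#'   representatives.
#' @export
syntheticExonFamily <- function(baseExon, nReps = 3L, divergence = 0.1,
                                seed = 1L) {
    stopifnot(nchar(baseExon) %% 3L == 0L, nReps >= 2L)
    seqs <- with_seed(seed, vapply(seq_len(nReps), function(i) {
        repeat {
            m <- mutate_nt(baseExon, divergence)
            if (!contains_stop_in_frame(m$seq)) break
        }
        as.character(Biostrings::translate(Biostrings::DNAString(m$seq)))
    }, character(1)))
    s <- Biostrings::AAStringSet(seqs)
    names(s) <- sprintf("rep%d", seq_len(nReps))
    new("AnnotatedAlignment", sequences = s, boundaries = list())
}

#' Genomic intervals of planted blocks
#'
#' Maps each block's residue span on the planted protein through the
#' exon/intron layout of a plant to forward-strand genomic intervals.
#' Assumes an ungapped training alignment (block columns = residue
#' coordinates), as produced by [syntheticFamily()].
#'
#' @param blocks List of [BlockDefinition-class].
#' @param plant The plant list used with [plantGene()].
#' @return `GRanges`, one interval per block (metadata column `block`).
#' @export
plantBlockIntervals <- function(blocks, plant) {
    exon_nt <- 3L * plant$exonPlan
    aa_ends <- cumsum(plant$exonPlan)
    aa_starts <- c(1L, head(aa_ends, -1L) + 1L)
    # construct-local 0-based start of each exon
    exon_off <- cumsum(c(0L, head(exon_nt + c(plant$intronLens, 0L), -1L)))
    total <- sum(exon_nt) + sum(plant$intronLens)
    strand <- if (!is.null(plant$strand)) plant$strand else "+"

    res <- lapply(blocks, function(b) {
        r0 <- b@colStart; r1 <- b@colEnd  # residues, 1-based closed
        e <- which(aa_starts <= r0 & r1 <= aa_ends)
        if (length(e) != 1L)
            stopf("block %d crosses an exon boundary of the plant", b@index)
        c0 <- exon_off[e] + 3L * (r0 - aa_starts[e])       # 0-based
        c1 <- exon_off[e] + 3L * (r1 - aa_starts[e] + 1L)
        if (strand == "-") {
            f0 <- plant$offset + total - c1; f1 <- plant$offset + total - c0
        } else {
            f0 <- plant$offset + c0; f1 <- plant$offset + c1
        }
        GenomicRanges::GRanges(plant$scaffold,
                               IRanges::IRanges(f0 + 1L, f1),
                               strand, block = b@index)
    })
    suppressWarnings(do.call(c, res))
}

#' Overwrite genomic intervals with random nucleotides
#'
#' Used to ablate planted blocks when probing the k-of-n rule: the
#' interval's sequence is replaced by uniform random nt.
#'
#' @param genome `DNAStringSet`.
#' @param gr `GRanges` of intervals to overwrite.
#' @param seed Integer seed.
#' @return Modified `DNAStringSet`.
#' @export
ablateIntervals <- function(genome, gr, seed = 1L) {
    seqs <- as.character(genome)
    with_seed(seed, {
        for (i in seq_along(gr)) {
            sc <- as.character(GenomeInfoDb::seqnames(gr))[i]
            s <- BiocGenerics::start(gr)[i]; e <- BiocGenerics::end(gr)[i]
            repl <- paste(sample(c("A", "C", "G", "T"), e - s + 1L,
                                 replace = TRUE), collapse = "")
            seqs[[sc]] <- paste0(substring(seqs[[sc]], 1L, s - 1L), repl,
                                 substring(seqs[[sc]], e + 1L))
        }
    })
    Biostrings::DNAStringSet(seqs)
}

#' Build a complete seeded benchmark fixture
#'
#' One call emits the whole synthetic study design: a block-training
#' family alignment with exon boundaries, a positive genome with one
#' planted multi-exon gene (derived from the family ancestor) and three
#' exon-variant arrays, a negative random genome, and an
#' `expected.json` manifest of truth counts.  Every artefact is a pure
#' function of the config and seed.
#'
#' @param config Named list; any subset of: `seed` (1), `nSeqs` (5),
#'   `nExons` (10), `exonLenAA` (60), `famDivergence` (0.15), `nBlocks`
#'   (10), `blockMin` (20), `blockMax` (30), `intronLen` (200),
#'   `mutationRate` (0), `posScaffolds` (5), `posLen` (30000),
#'   `negScaffolds` (1000), `negLen` (30000), `gc` (0.5),
#'   `arraySizes` (`c(Ig2 = 12, Ig3 = 48, Ig7 = 33)`), `exonLenNT`
#'   (150), `arrayDivergence` (0.1), `spacerLen` (60).
#' @param dir Optional output directory; when given, writes
#'   `genome.fasta`, `negative.fasta`, `truth.gff3`, `blocks/`
#'   (training alignment, boundary table, `blocks.json`) and
#'   `expected.json`.
#' @return List with `family`, `blocks`, `positive` (genome + truth),
#'   `negative`, `plant` (the gene plant spec), `regions` (`GRanges`, one
#'   interval per cluster spanning its array, usable directly with
#'   [scanExonVariants()]), `expected` (truth counts), and `dir` (or
#'   `NULL`).
#' @export
benchmarkBundle <- function(config = list(), dir = NULL) {
    cfg <- utils::modifyList(list(
        seed = 1L, nSeqs = 5L, nExons = 10L, exonLenAA = 60L,
        famDivergence = 0.15, nBlocks = 10L, blockMin = 20L, blockMax = 30L,
        intronLen = 200L, mutationRate = 0, posScaffolds = 5L,
        posLen = 30000L, negScaffolds = 1000L, negLen = 30000L, gc = 0.5,
        arraySizes = c(Ig2 = 12L, Ig3 = 48L, Ig7 = 33L),
        exonLenNT = 150L, arrayDivergence = 0.1, spacerLen = 60L),
        config)
    seed <- cfg$seed

    fam <- syntheticFamily(seed = derive_seed(seed, "family"),
                           nSeqs = cfg$nSeqs, nExons = cfg$nExons,
                           exonLenAA = cfg$exonLenAA,
                           divergence = cfg$famDivergence)
    blocks <- extractBlocks(fam$alignment, cfg$nBlocks, cfg$blockMin,
                            cfg$blockMax)

    pos <- randomGenome(cfg$posScaffolds, cfg$posLen, gc = cfg$gc,
                        seed = derive_seed(seed, "pos"))
    plant <- list(protein = fam$ancestor, exonPlan = fam$exonPlan,
                  intronLens = rep(cfg$intronLen, cfg$nExons - 1L),
                  mutationRate = cfg$mutationRate,
                  scaffold = names(pos$genome)[1], offset = 1000L,
                  strand = "+", id = "gene1", source = "ancestor")
    pos <- plantGene(pos$genome, plant, seed = derive_seed(seed, "gene"),
                     truth = pos$truth)

    # cluster arrays on scaffold 2, spaced well apart
    base_exons <- with_seed(derive_seed(seed, "exons"), {
        lapply(seq_along(cfg$arraySizes), function(i) {
            repeat {
                e <- paste(sample(c("A", "C", "G", "T"), cfg$exonLenNT,
                                  replace = TRUE), collapse = "")
                if (!contains_stop_in_frame(e)) return(e)
            }
        })
    })
    names(base_exons) <- names(cfg$arraySizes)
    arr_scaffold <- names(pos$genome)[2]
    offset <- 500L
    regions <- list()
    for (cl in names(cfg$arraySizes)) {
        n <- cfg$arraySizes[[cl]]
        span <- n * cfg$exonLenNT + (n - 1L) * cfg$spacerLen
        pos <- plantExonArray(pos$genome, base_exons[[cl]], n,
                              cfg$arrayDivergence, cfg$spacerLen,
                              arr_scaffold, offset, strand = "+",
                              cluster = cl,
                              seed = derive_seed(seed, paste0("arr", cl)),
                              truth = pos$truth)
        regions[[cl]] <- GenomicRanges::GRanges(
            arr_scaffold,
            IRanges::IRanges(max(1L, offset - 200L), offset + span + 200L),
            "+", cluster = cl)
        offset <- offset + span + 2000L
    }
    regions <- suppressWarnings(do.call(c, unname(regions)))

    neg <- randomGenome(cfg$negScaffolds, cfg$negLen, gc = cfg$gc,
                        seed = derive_seed(seed, "neg"), prefix = "rand")

    expected <- list(
        planted_genes = 1L,
        planted_blocks = length(blocks),
        variant_counts = as.list(setNames(as.integer(cfg$arraySizes),
                                          names(cfg$arraySizes))))

    out <- list(family = fam, blocks = blocks, positive = pos,
                negative = neg, plant = plant, baseExons = base_exons,
                regions = regions, expected = expected, config = cfg,
                dir = dir)
    if (!is.null(dir)) {
        dir.create(file.path(dir, "blocks"), recursive = TRUE,
                   showWarnings = FALSE)
        Biostrings::writeXStringSet(pos$genome,
                                    file.path(dir, "genome.fasta"))
        Biostrings::writeXStringSet(neg$genome,
                                    file.path(dir, "negative.fasta"))
        writeTruthGFF3(pos$truth, file.path(dir, "truth.gff3"))
        Biostrings::writeXStringSet(fam$alignment@sequences,
                                    file.path(dir, "blocks", "family.fasta"))
        bl <- vapply(names(fam$alignment@boundaries), function(id)
            paste(id, paste(fam$alignment@boundaries[[id]], collapse = ","),
                  sep = "\t"), character(1))
        writeLines(bl, file.path(dir, "blocks", "boundaries.tsv"))
        writeBlocksJSON(blocks, file.path(dir, "blocks", "blocks.json"))
        jsonlite::write_json(expected, file.path(dir, "expected.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    out
}
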
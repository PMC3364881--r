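test_that("six-frame translation handles direct, reverse and stop-split cases", {
    fw <- sixFrameTranslate("ATGAAA")
    mk <- fw[fw$strand == "+" & fw$frame == 0, ]
    expect_equal(mk$aa, "MK")
    expect_equal(c(mk$nt_start, mk$nt_end), c(0L, 6L))

    rv <- sixFrameTranslate("TTTCAT")
    mk2 <- rv[rv$strand == "-" & rv$frame == 0, ]
    expect_equal(mk2$aa, "MK")
    expect_equal(c(mk2$nt_start, mk2$nt_end), c(0L, 6L))

    sp <- sixFrameTranslate("ATGTAAATG")
    f0 <- sp[sp$strand == "+" & sp$frame == 0, ]
    expect_equal(f0$aa, c("M", "M"))
    expect_equal(f0$nt_start, c(0L, 6L))
    expect_equal(f0$nt_end, c(3L, 9L))

    expect_equal(nrow(sixFrameTranslate("AT")), 0L)
})

test_that("segment coordinates round-trip through the genome sequence", {
    set.seed(41)
    for (rep in 1:3) {
        nt <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                           prob = c(.24, .24, .24, .24, .04)), collapse = "")
        segs <- sixFrameTranslate(nt, id = "s")
        expect_true(all(segs$nt_end - segs$nt_start == 3L * nchar(segs$aa)))
        expect_false(any(grepl("\\*", segs$aa)))
        for (i in seq_len(nrow(segs))) {
            sl <- Biostrings::DNAString(substring(nt, segs$nt_start[i] + 1L,
                                                  segs$nt_end[i]))
            if (segs$strand[i] == "-") sl <- Biostrings::reverseComplement(sl)
            expect_equal(as.character(Biostrings::translate(
                sl, if.fuzzy.codon = "X", no.init.codon = TRUE)), segs$aa[i])
        }
    }
})

test_that("a planted consensus is found at its exact coordinates on both strands", {
    bs <- fx_blockset()
    hmm <- blockHMMs(bs)[[1]]
    cons_nt <- back_translate_simple(profile_consensus(hmm), seed = 51)
    set.seed(52)
    flank1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = "")
    flank2 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = "")
    g_fwd <- Biostrings::DNAStringSet(paste0(flank1, cons_nt, flank2))
    names(g_fwd) <- "scf"
    hits <- scanGenome(bs, g_fwd, eCutoff = 0.001)
    h1 <- hits[hits$block == 1]
    expect_equal(length(h1), 1L)
    expect_equal(BiocGenerics::start(h1), 301L)
    expect_equal(BiocGenerics::end(h1), 300L + nchar(cons_nt))
    expect_equal(as.character(BiocGenerics::strand(h1)), "+")

    g_rev <- Biostrings::DNAStringSet(as.character(
        Biostrings::reverseComplement(g_fwd[[1]])))
    names(g_rev) <- "scf"
    hits_r <- scanGenome(bs, g_rev, eCutoff = 0.001)
    hr <- hits_r[hits_r$block == 1]
    expect_equal(as.character(BiocGenerics::strand(hr)), "-")
    expect_equal(hr$score, h1$score)
})

test_that("all-N scaffolds yield no hits", {
    g <- Biostrings::DNAStringSet(strrep("N", 3000))
    names(g) <- "nn"
    expect_length(scanGenome(fx_blockset(), g, eCutoff = 0.01), 0L)
})

test_that("scan output does not depend on scaffold order", {
    bs <- fx_blockset()
    h1 <- blockHMMs(bs)[[1]]; h2 <- blockHMMs(bs)[[2]]
    g <- Biostrings::DNAStringSet(c(
        a = paste0(strrep("T", 90),
                   back_translate_simple(profile_consensus(h1), 61),
                   strrep("T", 90)),
        b = paste0(strrep("T", 90),
                   back_translate_simple(profile_consensus(h2), 62),
                   strrep("T", 90))))
    hits_ab <- scanGenome(bs, g, eCutoff = 0.01)
    hits_ba <- scanGenome(bs, rev(g), eCutoff = 0.01)
    expect_equal(as.data.frame(hits_ab), as.data.frame(hits_ba))
})

test_that("collinear candidate calling matches the exhaustive oracle", {
    # in-order plant: all ten blocks collinear
    gr10 <- GenomicRanges::GRanges("s", IRanges::IRanges(100 * (1:10) + 1,
                                                         width = 60),
        strand = "+", block = 1:10, frame = 0L, score = rep(50, 10),
        evalue = rep(1e-8, 10), aaSeq = rep("A", 10))
    cand <- callCandidates(gr10, nBlocks = 10, kMin = 6)
    expect_length(cand, 1L)
    expect_equal(cand$matchedInOrder, 10L)

    # blocks 3 and 7 swapped in genomic position: best chain drops to 8
    pos_order <- c(1, 2, 7, 4, 5, 6, 3, 8, 9, 10)
    gr8 <- gr10
    GenomicRanges::ranges(gr8) <- IRanges::IRanges(
        start = 100 * order(pos_order) + 1, width = 60)
    cand8 <- callCandidates(gr8, nBlocks = 10, kMin = 6)
    expect_equal(cand8$matchedInOrder, 8L)
    ora <- oracle_best_collinear(gr8$block,
        (BiocGenerics::start(gr8) + BiocGenerics::end(gr8)) / 2, gr8$score)
    expect_equal(ora$count, 8L)

    # below threshold: no candidate
    expect_length(callCandidates(gr8, nBlocks = 10, kMin = 9), 0L)

    # reverse-strand plant: decreasing order is the correct one
    grm <- gr10
    BiocGenerics::strand(grm) <- "-"
    grm$block <- 10:1
    candm <- callCandidates(grm, nBlocks = 10, kMin = 6)
    expect_equal(candm$matchedInOrder, 10L)
})

test_that("candidate chains agree with the oracle across random instances", {
    for (seed in 1:60) {
        gr <- random_hit_instance(seed)
        cand <- callCandidates(gr, nBlocks = 10, kMin = 1)
        ora <- oracle_best_collinear(gr$block,
            (BiocGenerics::start(gr) + BiocGenerics::end(gr)) / 2, gr$score)
        expect_equal(cand$matchedInOrder, ora$count, info = paste("seed", seed))
        # matched_in_order never exceeds the number of distinct hit blocks
        expect_lte(cand$matchedInOrder, length(unique(gr$block)))
    }
})

test_that("gene-model chaining picks the best alternatives and matches brute force", {
    one <- random_hit_instance(999)[1]
    ch1 <- chainGeneModel(one)
    expect_length(ch1$chain, 1L)
    expect_equal(ch1$protein, one$aaSeq)

    # two alternatives for one block: the higher-scoring chainable hit wins
    gr <- GenomicRanges::GRanges("s", IRanges::IRanges(c(101, 501, 901),
                                                       width = 60),
        strand = "+", block = c(1L, 1L, 2L), frame = 0L,
        score = c(20, 30, 40), evalue = rep(1e-6, 3),
        aaSeq = c("AA", "BB", "CC"))
    ch <- chainGeneModel(gr, gapPenalty = 1e-4)
    expect_equal(ch$chain$score, c(30, 40))

    for (seed in 61:120) {
        gr <- random_hit_instance(seed)
        ch <- suppressWarnings(chainGeneModel(gr, gapPenalty = 0.001))
        ora <- oracle_best_chain(gr$block, BiocGenerics::start(gr),
                                 BiocGenerics::end(gr), gr$score, 0.001)
        expect_equal(ch$score, ora, tolerance = 1e-9,
                     info = paste("seed", seed))
    }
})

test_that("hit coordinates always translate back to the matched residues", {
    bs <- fx_blockset()
    b <- benchmarkBundle(list(seed = 5L, negScaffolds = 1L, posScaffolds = 3L))
    bset <- calibrate(buildBlockSet(b$blocks), nSamples = 2000L,
                      sampleLen = 100L, seed = 404)
    hits <- scanGenome(bset, b$positive$genome, eCutoff = 0.001)
    expect_gte(length(hits), 10L)
    for (i in seq_along(hits)) {
        nt <- Biostrings::subseq(
            b$positive$genome[[as.character(GenomeInfoDb::seqnames(hits))[i]]],
            BiocGenerics::start(hits)[i], BiocGenerics::end(hits)[i])
        if (as.character(BiocGenerics::strand(hits))[i] == "-")
            nt <- Biostrings::reverseComplement(nt)
        expect_equal(as.character(Biostrings::translate(nt,
            if.fuzzy.codon = "X", no.init.codon = TRUE)), hits$aaSeq[i])
    }
})

test_that("planted-gene recovery degrades monotonically with mutation rate", {
    fam <- fx_family()
    bs <- fx_blockset()
    rates <- c(0, 0.05, 0.10, 0.20)
    matched <- vapply(rates, function(r) {
        g <- randomGenome(2, 30000, seed = 71)
        pl <- list(protein = fam$ancestor, exonPlan = fam$exonPlan,
                   intronLens = rep(150L, 9L), mutationRate = r,
                   scaffold = "scaffold1", offset = 2000L, strand = "+")
        g <- plantGene(g$genome, pl, seed = 72, truth = g$truth)
        hits <- scanGenome(bs, g$genome, eCutoff = 0.001)
        cand <- callCandidates(hits, nBlocks = 10, kMin = 1)
        if (length(cand) == 0L) 0L else max(cand$matchedInOrder)
    }, integer(1))
    expect_equal(matched[1], 10L)
    expect_true(all(diff(matched) <= 0))
})
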
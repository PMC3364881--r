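test_that("intronic regions fall between consecutive anchors", {
    anchors <- GenomicRanges::GRanges("s",
        IRanges::IRanges(c(101, 501), c(200, 600)), "+",
        cluster = c("Ig2", "Ig2"))
    r <- extractIntronicRegions(anchors)
    expect_length(r, 1L)
    expect_equal(BiocGenerics::start(r), 201L)
    expect_equal(BiocGenerics::end(r), 500L)
    expect_equal(r$cluster, "Ig2")

    # adjacent anchors leave no region
    adj <- GenomicRanges::GRanges("s",
        IRanges::IRanges(c(101, 201), c(200, 300)), "+",
        cluster = c("Ig3", "Ig3"))
    expect_length(extractIntronicRegions(adj), 0L)

    # out-of-order or overlapping anchors are rejected
    bad <- GenomicRanges::GRanges("s",
        IRanges::IRanges(c(501, 101), c(600, 200)), "+",
        cluster = c("Ig7", "Ig7"))
    expect_error(extractIntronicRegions(bad), "out of order")
    ovl <- GenomicRanges::GRanges("s",
        IRanges::IRanges(c(101, 150), c(200, 300)), "+",
        cluster = c("Ig7", "Ig7"))
    expect_error(extractIntronicRegions(ovl), "overlap")
})

# shared small array fixture: 12 variants at 10% divergence plus a
# 3-representative training set from the same base exon
fx_array <- function() fx("array", function() {
    base <- fx("base_exon", function() {
        set.seed(81)
        repeat {
            e <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                       collapse = "")
            if (!dscamtools:::contains_stop_in_frame(e)) return(e)
        }
    })
    g <- randomGenome(1, 20000, seed = 82)
    g <- plantExonArray(g$genome, base, 12, 0.1, 60, "scaffold1", 3000,
                        cluster = "Ig2", seed = 83, truth = g$truth)
    reps <- syntheticExonFamily(base, 3, divergence = 0.1, seed = 84)
    hmm <- calibrate(buildProfile(reps, name = "Ig2"), nSamples = 2000L,
                     sampleLen = 60L, seed = 85)
    regions <- GenomicRanges::GRanges("scaffold1",
        IRanges::IRanges(2500, 6500), "+", cluster = "Ig2")
    list(genome = g$genome, truth = g$truth, hmm = hmm, regions = regions,
         base = base)
})

test_that("planted exon variants are all recovered with matching intervals", {
    a <- fx_array()
    hits <- scanExonVariants(list(Ig2 = a$hmm), a$regions, a$genome,
                             eCutoff = 0.001)
    expect_equal(length(hits), 12L)
    expect_true(all(!hits$inverted))
    truth_vars <- a$truth[a$truth$type == "variant"]
    ov <- GenomicRanges::countOverlaps(truth_vars, hits)
    expect_true(all(ov >= 1))
    # kept hits never overlap each other by more than half the shorter
    if (length(hits) > 1) {
        hp <- GenomicRanges::findOverlaps(hits, hits)
        hp <- hp[S4Vectors::queryHits(hp) < S4Vectors::subjectHits(hp)]
        for (k in seq_along(hp)) {
            i <- S4Vectors::queryHits(hp)[k]; j <- S4Vectors::subjectHits(hp)[k]
            w <- IRanges::width(IRanges::pintersect(
                IRanges::ranges(hits)[i], IRanges::ranges(hits)[j]))
            expect_lte(w, 0.5 * min(IRanges::width(hits)[c(i, j)]))
        }
    }
})

test_that("variant hit sequences translate without stops", {
    a <- fx_array()
    hits <- scanExonVariants(list(Ig2 = a$hmm), a$regions, a$genome,
                             eCutoff = 0.001)
    for (i in seq_along(hits)) {
        nt <- Biostrings::DNAString(hits$ntSeq[i])
        aa <- Biostrings::translate(Biostrings::subseq(
            nt, 1, 3L * (length(nt) %/% 3L)), if.fuzzy.codon = "X",
            no.init.codon = TRUE)
        expect_false(grepl("\\*", as.character(aa)))
    }
})

test_that("an inverted variant is flagged", {
    a <- fx_array()
    # plant one extra reverse-complemented copy downstream in the region
    g2 <- plantExonArray(a$genome, a$base, 1, 0, 60, "scaffold1", 6000,
                         strand = "-", cluster = "Ig2", seed = 86,
                         truth = a$truth)
    hits <- scanExonVariants(list(Ig2 = a$hmm), a$regions, g2$genome,
                             eCutoff = 0.001)
    expect_equal(length(hits), 13L)
    inv <- hits[hits$inverted]
    expect_equal(length(inv), 1L)
    expect_equal(as.character(BiocGenerics::strand(inv)), "-")
    # retrieved sequence is the reverse complement of the genome slice
    sl <- Biostrings::subseq(g2$genome[["scaffold1"]],
                             BiocGenerics::start(inv), BiocGenerics::end(inv))
    expect_equal(inv$ntSeq,
                 as.character(Biostrings::reverseComplement(sl)))
})

test_that("random intronic sequence yields no variant hits at the default cutoff", {
    a <- fx_array()
    zero <- vapply(1:20, function(s) {
        g <- randomGenome(1, 5000, seed = 900 + s)
        regions <- GenomicRanges::GRanges("scaffold1",
            IRanges::IRanges(1, 5000), "+", cluster = "Ig2")
        length(scanExonVariants(list(Ig2 = a$hmm), regions, g$genome,
                                eCutoff = 0.001)) == 0L
    }, logical(1))
    expect_gte(mean(zero), 0.95)
})

test_that("variant counts shrink as the cutoff tightens", {
    a <- fx_array()
    n_loose <- length(scanExonVariants(list(Ig2 = a$hmm), a$regions,
                                       a$genome, eCutoff = 0.01))
    n_main <- length(scanExonVariants(list(Ig2 = a$hmm), a$regions,
                                      a$genome, eCutoff = 0.001))
    n_tight <- length(scanExonVariants(list(Ig2 = a$hmm), a$regions,
                                       a$genome, eCutoff = 1e-6))
    expect_gte(n_loose, n_main)
    expect_gte(n_main, n_tight)
})

test_that("variant summaries tabulate all clusters including empty ones", {
    a <- fx_array()
    hits <- scanExonVariants(list(Ig2 = a$hmm), a$regions, a$genome,
                             eCutoff = 0.001)
    tab <- variantSummary(hits, genomeId = "synthetic")
    expect_equal(tab$n[tab$cluster == "Ig2"], 12L)
    expect_equal(tab$n[tab$cluster == "Ig3"], 0L)
    expect_equal(tab$n[tab$cluster == "Ig7"], 0L)
    empty <- variantSummary(scanExonVariants(list(Ig2 = a$hmm),
        a$regions[0], a$genome, eCutoff = 0.001))
    expect_true(all(empty$n == 0L))
})
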
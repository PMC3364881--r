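test_that("random genomes are seed-reproducible with correct shape and composition", {
    g1 <- randomGenome(10, 1000, seed = 1)
    g2 <- randomGenome(10, 1000, seed = 1)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    expect_false(identical(as.character(g1$genome),
                           as.character(randomGenome(10, 1000, seed = 2)$genome)))
    expect_length(g1$genome, 10L)
    expect_true(all(Biostrings::width(g1$genome) == 1000L))
    expect_length(g1$truth, 0L)

    g <- randomGenome(1, 30000, gc = 0.5, seed = 3)
    counts <- Biostrings::alphabetFrequency(g$genome[[1]])
    gc_obs <- sum(counts[c("G", "C")]) / 30000
    expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 30000))

    gskew <- randomGenome(1, 30000, gc = 0.2, seed = 4)
    counts2 <- Biostrings::alphabetFrequency(gskew$genome[[1]])
    expect_lt(abs(sum(counts2[c("G", "C")]) / 30000 - 0.2),
              3 * sqrt(0.2 * 0.8 / 30000))

    expect_error(randomGenome(0, 100), "invalid genome spec")
    expect_error(randomGenome(1, 2), "invalid genome spec")
})

make_plant <- function(fam, rate = 0, strand = "+", offset = 1000L) {
    list(protein = fam$ancestor, exonPlan = fam$exonPlan,
         intronLens = rep(100L, length(fam$exonPlan) - 1L),
         mutationRate = rate, scaffold = "scaffold1", offset = offset,
         strand = strand)
}

recover_protein <- function(genome, truth) {
    ex <- truth[truth$type == "exon"]
    ex <- ex[order(ex$exonIndex)]
    pieces <- vapply(seq_along(ex), function(i) {
        nt <- Biostrings::subseq(
            genome[[as.character(GenomeInfoDb::seqnames(ex))[i]]],
            BiocGenerics::start(ex)[i], BiocGenerics::end(ex)[i])
        if (as.character(BiocGenerics::strand(ex))[i] == "-")
            nt <- Biostrings::reverseComplement(nt)
        as.character(nt)
    }, character(1))
    as.character(Biostrings::translate(
        Biostrings::DNAString(paste(pieces, collapse = "")),
        no.init.codon = TRUE))
}

test_that("unmutated planted genes reproduce the source protein from truth exons", {
    fam <- fx_family()
    for (strand in c("+", "-")) {
        g <- randomGenome(2, 12000, seed = 11)
        res <- plantGene(g$genome, make_plant(fam, strand = strand),
                         seed = 12, truth = g$truth)
        expect_equal(recover_protein(res$genome, res$truth), fam$ancestor)
        expect_equal(sum(res$truth$type == "exon"), 10L)
        gene <- res$truth[res$truth$type == "gene"]
        expect_equal(gene$mutations, 0L)
    }
})

test_that("planted introns start GT, end AG and stop in the upstream frame within 9 nt", {
    fam <- fx_family()
    g <- randomGenome(1, 12000, seed = 13)
    res <- plantGene(g$genome, make_plant(fam), seed = 14, truth = g$truth)
    ex <- res$truth[res$truth$type == "exon"]
    ex <- ex[order(ex$exonIndex)]
    for (i in seq_len(length(ex) - 1L)) {
        intron <- as.character(Biostrings::subseq(res$genome[["scaffold1"]],
            BiocGenerics::end(ex)[i] + 1L, BiocGenerics::start(ex)[i + 1L] - 1L))
        expect_equal(substr(intron, 1, 2), "GT")
        expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
        lead <- substr(intron, 1, 9)
        codons <- substring(lead, c(1, 4, 7), c(3, 6, 9))
        expect_true(any(codons %in% c("TAA", "TAG", "TGA")))
    }
})

test_that("substitution counts concentrate around rate x length", {
    fam <- fx_family()
    g <- randomGenome(1, 12000, seed = 15)
    res <- plantGene(g$genome, make_plant(fam, rate = 0.1), seed = 16,
                     truth = g$truth)
    total_nt <- 3 * sum(fam$exonPlan) + 100 * 9
    nmut <- res$truth$mutations[res$truth$type == "gene"]
    expect_lt(abs(nmut - 0.1 * total_nt), 3 * sqrt(total_nt * 0.1 * 0.9))
})

test_that("exon arrays honour their spec and mutation algebra", {
    base <- fx("base_exon", function() {
        set.seed(81)
        repeat {
            e <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                       collapse = "")
            if (!dscamtools:::contains_stop_in_frame(e)) return(e)
        }
    })
    g <- randomGenome(1, 30000, seed = 21)
    res <- plantExonArray(g$genome, base, 48, 0, 60, "scaffold1", 500,
                          seed = 22, truth = g$truth)
    vars <- res$truth[res$truth$type == "variant"]
    expect_length(vars, 48L)
    expect_equal(BiocGenerics::start(vars), 501L + (0:47) * 210L)
    seqs <- vapply(seq_along(vars), function(i)
        as.character(Biostrings::subseq(res$genome[["scaffold1"]],
            BiocGenerics::start(vars)[i], BiocGenerics::end(vars)[i])),
        character(1))
    expect_true(all(seqs == base))

    # with divergence d, expected pairwise identity ~ (1-d)^2 + d^2/3
    d <- 0.1
    res2 <- plantExonArray(g$genome, base, 30, d, 60, "scaffold1", 15000,
                           seed = 23, truth = g$truth)
    v2 <- res2$truth[res2$truth$type == "variant"]
    seqs2 <- vapply(seq_along(v2), function(i)
        strsplit(as.character(Biostrings::subseq(res2$genome[["scaffold1"]],
            BiocGenerics::start(v2)[i], BiocGenerics::end(v2)[i])), "")[[1]],
        character(150))
    idents <- c()
    for (i in 1:10) for (j in (i + 1):11)
        idents <- c(idents, mean(seqs2[, i] == seqs2[, j]))
    expected <- (1 - d)^2 + d^2 / 3
    expect_lt(abs(mean(idents) - expected), 0.03)

    # truth count equals n for any parameters
    res3 <- plantExonArray(g$genome, base, 5, 0.3, 10, "scaffold1", 25000,
                           seed = 24, truth = g$truth)
    expect_equal(sum(res3$truth$type == "variant"), 5L)
})

test_that("overlapping plants are refused", {
    fam <- fx_family()
    g <- randomGenome(1, 20000, seed = 31)
    res <- plantGene(g$genome, make_plant(fam), seed = 32, truth = g$truth)
    expect_error(plantGene(res$genome, make_plant(fam, offset = 1500L),
                           seed = 33, truth = res$truth), "overlaps")
})

test_that("planted block intervals carry the block sequences", {
    fam <- fx_family()
    blocks <- fx_blocks()
    g <- randomGenome(1, 12000, seed = 41)
    plant <- make_plant(fam)
    res <- plantGene(g$genome, plant, seed = 42, truth = g$truth)
    gr <- plantBlockIntervals(blocks, plant)
    expect_length(gr, length(blocks))
    for (i in seq_along(gr)) {
        nt <- Biostrings::subseq(res$genome[["scaffold1"]],
            BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i])
        aa <- as.character(Biostrings::translate(nt, no.init.codon = TRUE))
        ref <- substr(fam$ancestor, blocks[[i]]@colStart, blocks[[i]]@colEnd)
        expect_equal(aa, ref)
    }
})

test_that("the benchmark bundle is complete, consistent and reproducible", {
    dir <- file.path(tempdir(), "bundle-test")
    cfg <- list(seed = 9L, negScaffolds = 1L, posScaffolds = 3L,
                arraySizes = c(Ig2 = 4L, Ig3 = 6L, Ig7 = 5L))
    b <- benchmarkBundle(cfg, dir = dir)
    expect_true(all(file.exists(file.path(dir,
        c("genome.fasta", "negative.fasta", "truth.gff3", "expected.json",
          "blocks/family.fasta", "blocks/boundaries.tsv",
          "blocks/blocks.json")))))
    expect_equal(b$expected$planted_genes, 1L)
    expect_equal(b$expected$variant_counts$Ig3, 6L)
    expect_equal(sum(b$positive$truth$type == "variant"), 15L)
    # truth/FASTA consistency and determinism
    b2 <- benchmarkBundle(cfg)
    expect_identical(as.character(b$positive$genome),
                     as.character(b2$positive$genome))
    expect_equal(recover_protein(b$positive$genome,
        b$positive$truth[!is.na(b$positive$truth$exonIndex) |
                         b$positive$truth$type == "gene"]),
        b$family$ancestor)
    # planted intervals never overlap
    spans <- b$positive$truth[b$positive$truth$type %in% c("gene", "array")]
    expect_equal(max(GenomicRanges::countOverlaps(spans, spans)), 1L)
})
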
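test_that("profile estimator matches hand-computed values", {
    # identical rows, no pseudocounts: deterministic emissions
    aln <- make_aln(list(a = "ACDEF", b = "ACDEF", c = "ACDEF"))
    h <- buildProfile(aln, alpha = 0)
    expect_equal(hmmLength(h), 5L)
    M <- matchEmissions(h)
    for (j in 1:5)
        expect_equal(unname(M[j, substr("ACDEF", j, j)]), 1)

    # a column gapped in 2 of 3 rows is not a match state
    aln2 <- make_aln(list(a = "A-CDE", b = "A-CDE", c = "AKCDE"))
    expect_equal(hmmLength(buildProfile(aln2, alpha = 0)), 4L)

    # 4 rows, one substitution, alpha = 1, uniform background:
    # majority emission = (3 + 1/20) / (4 + 1) = 0.61
    aln3 <- make_aln(list(a = "AC", b = "AC", c = "AC", d = "AD"))
    h3 <- buildProfile(aln3, alpha = 1, background = uniformBackground())
    expect_equal(unname(matchEmissions(h3)[2, "C"]), (3 + 1 / 20) / 5)
    expect_equal(unname(matchEmissions(h3)[2, "D"]), (1 + 1 / 20) / 5)
})

test_that("emission and transition groups stay normalized through a file round-trip", {
    h <- fx_hmm()
    expect_true(all(abs(rowSums(matchEmissions(h)) - 1) < 1e-9))
    tr <- h@transitions
    expect_true(all(abs(rowSums(tr[, c("MM", "MI", "MD")]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(tr[, c("IM", "II")]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(tr[, c("DM", "DD")]) - 1) < 1e-9))
    p <- tempfile(fileext = ".hmm")
    writeProfile(h, p)
    h2 <- readProfile(p)
    expect_equal(matchEmissions(h2), matchEmissions(h), tolerance = 1e-12)
    expect_equal(h2@transitions, h@transitions, tolerance = 1e-12)
    expect_equal(calibration(h2), calibration(h), tolerance = 1e-12)
    expect_equal(hmmName(h2), hmmName(h))
})

test_that("viterbi prefers the consensus and spans a self-match", {
    h <- buildProfile(fx_blocks()[[2]])
    cons <- profile_consensus(h)
    rev_cons <- paste(rev(strsplit(cons, "")[[1]]), collapse = "")
    expect_gt(viterbi(h, cons)$score, viterbi(h, rev_cons)$score)

    # profile from one ungapped sequence scored on itself covers it fully
    seq1 <- random_aa(25, 9)
    h1 <- buildProfile(make_aln(list(a = seq1, b = seq1)), alpha = 0)
    v <- viterbi(h1, seq1)
    expect_equal(v$start, 1L)
    expect_equal(v$end, 25L)

    # local score never decreases when unrelated residues are appended
    for (s in 1:5) {
        tail_aa <- random_aa(30, 100 + s)
        expect_gte(viterbi(h, paste0(cons, tail_aa))$score,
                   viterbi(h, cons)$score)
    }

    # empty target
    e <- viterbi(h, "")
    expect_identical(e$score, -Inf)
    expect_equal(e$end, 0L)
})

test_that("forward dominates viterbi and collapses to it on a single path", {
    h <- fx_hmm()
    set.seed(21)
    for (i in 1:100) {
        s <- random_aa(sample(5:60, 1), sample.int(1e6, 1))
        expect_gte(forwardScore(h, s) + 1e-9, viterbi(h, s)$score)
    }
    # one match state, one residue: a single possible path
    h1 <- buildProfile(make_aln(list(a = "W", b = "W")), alpha = 0)
    expect_equal(forwardScore(h1, "W"), viterbi(h1, "W")$score,
                 tolerance = 1e-6)
})

test_that("forward separates consensus from shuffles", {
    h <- buildProfile(fx_blocks()[[3]])
    cons <- profile_consensus(h)
    fs <- forwardScore(h, cons)
    set.seed(31)
    chars <- strsplit(cons, "")[[1]]
    wins <- vapply(1:100, function(i)
        fs > forwardScore(h, paste(sample(chars), collapse = "")),
        logical(1))
    expect_gte(mean(wins), 0.95)
})

test_that("calibration is reproducible and satisfies the Gumbel location identity", {
    h <- buildProfile(fx_blocks()[[1]])
    c1 <- calibration(calibrate(h, nSamples = 500, sampleLen = 60, seed = 5))
    c2 <- calibration(calibrate(h, nSamples = 500, sampleLen = 60, seed = 5))
    expect_identical(c1, c2)
    c3 <- calibration(calibrate(h, nSamples = 500, sampleLen = 60, seed = 6))
    expect_false(identical(c1, c3))

    # P(score > mu) = 1 - exp(-1) ~ 0.632 on fresh nulls
    hc <- fx_hmm()
    mu <- calibration(hc)[["mu"]]
    set.seed(17)
    nulls <- vapply(1:1000, function(i)
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                     replace = TRUE, prob = robinsonBackground()),
              collapse = ""), character(1))
    scores <- dscamtools:::viterbiBatch(hc, nulls)[, 1]
    frac <- mean(scores > mu)
    # the Gumbel is an approximation to the true score null; the identity
    # holds to within the approximation bias plus sampling error
    expect_gt(frac, 0.632 - 0.08)
    expect_lt(frac, 0.632 + 0.08)

    # tail counts track nominal p-values
    pv <- gumbelPValue(scores, hc)
    for (p in c(0.1, 0.01)) {
        k <- sum(pv <= p)
        expect_gte(k, stats::qbinom(0.0005, 1000, p))
        expect_lte(k, stats::qbinom(0.9995, 1000, p))
    }
})

test_that("fitted null gives near-uniform p-values on fresh background sequences", {
    hc <- fx_hmm()
    set.seed(23)
    nulls <- vapply(1:1000, function(i) {
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                     replace = TRUE, prob = robinsonBackground()),
              collapse = "")
    }, character(1))
    pv <- gumbelPValue(dscamtools:::viterbiBatch(hc, nulls)[, 1], hc)
    ks <- suppressWarnings(stats::ks.test(pv, "punif"))
    # preset bound reflects the Gumbel bulk-approximation quality; the
    # binomial tail checks above are the sharp part of the contract
    expect_lt(unname(ks$statistic), 0.15)
})

test_that("evalues follow the closed form and scale with database size", {
    hc <- fx_hmm()
    mu <- calibration(hc)[["mu"]]
    expect_equal(evalue(mu, hc, 1), 1 - exp(-1), tolerance = 1e-12)
    s <- mu + 7
    expect_equal(evalue(s, hc, 2000), 2 * evalue(s, hc, 1000),
                 tolerance = 1e-12)
    expect_lt(evalue(s + 10, hc, 1000), evalue(s, hc, 1000))
    h_uncal <- buildProfile(fx_blocks()[[1]])
    expect_error(evalue(10, h_uncal, 100), "not calibrated")
})

test_that("degenerate training input fails loudly", {
    expect_error(buildProfile(make_aln(list(a = "--", b = "--", c = "AC"))),
                 "gap fraction")
    expect_error(calibrate(buildProfile(make_aln(list(a = "A", b = "A"))),
                           nSamples = 10),
                 "nSamples")
})
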
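# Brute-force oracles, independent of the package's dynamic programming:
# exhaustive DFS over all strictly collinear chains.

# best (count, total score) over all chains with strictly increasing block
# index and strictly increasing (or decreasing) midpoints
oracle_best_collinear <- function(block, mid, score, decreasing = FALSE) {
    m <- if (decreasing) -mid else mid
    n <- length(block)
    best_cnt <- 0L; best_sc <- -Inf
    rec <- function(last, cnt, sc) {
        if (cnt > best_cnt || (cnt == best_cnt && sc > best_sc)) {
            best_cnt <<- cnt; best_sc <<- sc
        }
        for (j in seq_len(n))
            if (block[j] > block[last] && m[j] > m[last])
                rec(j, cnt + 1L, sc + score[j])
    }
    for (i in seq_len(n)) rec(i, 1L, score[i])
    list(count = best_cnt, score = best_sc)
}

# best chain objective (sum of scores minus gap penalty) over all block-
# ordered, non-overlapping chains of 1-based closed intervals
oracle_best_chain <- function(block, s, e, score, gapPenalty) {
    n <- length(block)
    best <- -Inf
    rec <- function(last, sc) {
        best <<- max(best, sc)
        for (j in seq_len(n))
            if (block[j] > block[last] && s[j] > e[last])
                rec(j, sc + score[j] - gapPenalty * (s[j] - e[last] - 1))
    }
    for (i in seq_len(n)) rec(i, score[i])
    best
}

# random collinearity test instance on one scaffold/strand
random_hit_instance <- function(seed, max_hits = 12L, n_blocks = 10L) {
    set.seed(seed)
    n <- sample.int(max_hits, 1L)
    block <- sample.int(n_blocks, n, replace = TRUE)
    start <- sample.int(5000L, n)
    width <- sample(30:90, n, replace = TRUE)
    score <- round(runif(n, 5, 60), 3)
    GenomicRanges::GRanges("scf", IRanges::IRanges(start, width = width),
                           strand = "+", block = block, frame = 0L,
                           score = score, evalue = rep(1e-6, n),
                           aaSeq = rep("A", n))
}
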
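test_that("ALC and low-confidence-run filters match a brute-force oracle", {
    # threshold behaviour at the documented defaults
    p <- deNovoPeptideSet(c("PEPTIDER", "PEPTIDER"),
                          confidence = list(rep(0.69, 8), rep(0.71, 8)))
    kept <- filterPeptides(p)
    expect_length(kept, 1L)
    expect_equal(alcScores(kept), 0.71)
    # a fully confident peptide is always kept
    p2 <- deNovoPeptideSet("SEQVENCE")
    expect_length(filterPeptides(p2), 1L)

    set.seed(5)
    seqs <- replicate(200, randomSeq(sample(6:15, 1)))
    conf <- lapply(nchar(seqs), function(n) runif(n))
    ps <- deNovoPeptideSet(seqs, confidence = conf)
    got <- peptideSequences(filterPeptides(ps))
    oracle <- vapply(seq_along(seqs), function(i) {
        if (mean(conf[[i]]) <= 0.7) return(FALSE)
        runs <- rle(conf[[i]] < 0.5)
        bad <- runs$lengths[runs$values]
        length(bad) == 0 || max(bad) <= 4
    }, logical(1))
    expect_equal(got, seqs[oracle])
})

test_that("overlap edges require three mass blocks and match a pairwise oracle", {
    p <- deNovoPeptideSet(c("SEQVENCE", "EGGECPEP", "WWWHHH"))
    g <- buildOverlapGraph(p, minBlocks = 3L)
    ed <- graphEdges(g)
    expect_true(any(ed$from == 1 & ed$to == 2 & ed$nBlocks == 3))
    expect_false(any(ed$from == 1 & ed$to == 3))
    expect_false(any(ed$from == 3 & ed$to == 1))

    # tiling reads of a random chain: edge set agrees with the exhaustive
    # alignment oracle applied to every ordered pair
    set.seed(9)
    fx <- makeTilingFixture(L = 36L, nPep = 9L)
    g2 <- buildOverlapGraph(fx$peptides, minBlocks = 3L)
    ed2 <- graphEdges(g2)
    n <- length(fx$peptides)
    seqs <- peptideSequences(fx$peptides)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        o <- oracleAlign(seqs[i], seqs[j], minBlocks = 3L)
        # proper extension: B must reach beyond the overlap (its total mass
        # exceeds the overlapped suffix mass of A)
        proper <- !is.null(o) &&
            sum(parsePeptide(seqs[j])$mass) -
            sum(parsePeptide(substr(seqs[i], o$aStart,
                                    nchar(seqs[i])))$mass) > 1e-6
        hasEdge <- any(ed2$from == i & ed2$to == j)
        expect_equal(hasEdge, proper, info = paste(seqs[i], seqs[j]))
    }
})

test_that("confidence accumulation raises supported positions and never lowers any", {
    # isolated peptide: unchanged
    p0 <- deNovoPeptideSet("WWWHHHKKK", confidence = list(rep(0.6, 9)))
    g0 <- buildOverlapGraph(p0)
    expect_equal(accumulatedConfidence(g0)[[1]], rep(0.6, 9))

    # a poorly fragmented C-terminus boosted by a confident right extender
    p <- deNovoPeptideSet(c("PEPTIDEWK", "IDEWKHHHG"),
                          confidence = list(c(rep(0.9, 6), 0.3, 0.3, 0.3),
                                            rep(0.95, 9)))
    g <- buildOverlapGraph(p)
    acc <- accumulatedConfidence(g)
    expect_gt(acc[[1]][7], 0.3)
    expect_gt(acc[[1]][9], 0.3)
    # hand-computed: overlap IDEWK aligns one-to-one, so the boost is the
    # neighbour's positional score: min(1, 0.3 + 0.95)
    expect_equal(acc[[1]][7], min(1, 0.3 + 0.95))
    # never below the original local confidence
    for (i in seq_along(acc))
        expect_true(all(acc[[i]] + 1e-12 >= p@confidence[[i]]))

    # a symmetric overlapping pair updates both identically
    q <- deNovoPeptideSet(c("AAAGGGTTTCCC", "GGGTTTCCCAAA"),
                          confidence = list(rep(0.5, 12), rep(0.5, 12)))
    gq <- buildOverlapGraph(q)
    aq <- accumulatedConfidence(gq)
    expect_equal(aq[[1]], rev(rev(aq[[2]])))
})

test_that("terminus classification recovers simulated labels and rejects decoys", {
    set.seed(23)
    ch <- generateChains(2)
    bu <- emitBottomUp(ch, depth = 3, errorRate = 0)
    pep <- convertIleToLeu(bu$peptides)
    cls <- classifyTerminus(pep)
    truthLab <- bu$truth$label
    # spec-level target: at least 95 percent agreement on labelled reads
    expect_gte(mean(as.character(cls) == truthLab), 0.95)
    # middle-of-chain reads are OTHER
    mid <- truthLab == "OTHER"
    expect_gte(mean(cls[mid] == "OTHER"), 0.99)
    # reversed-sequence decoys match no profile
    dec <- deNovoPeptideSet(vapply(sample(peptideSequences(pep), 30),
        function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
        character(1)))
    expect_true(all(classifyTerminus(dec) == "OTHER"))
})

test_that("terminus sets partition the labelled classes by subunit type", {
    cls <- factor(c("LC-START", "LC-END", "Fd-START", "OTHER", "Fc/2-END"),
                  levels = levels(classifyTerminus(deNovoPeptideSet("PEPTIDE"))))
    ts <- terminusSets(cls)
    expect_equal(ts$LC$start, 1L)
    expect_equal(ts$LC$end, 2L)
    expect_equal(ts$Fd$start, 3L)
    expect_length(ts$Fc2$start, 0L)
    expect_equal(ts$Fc2$end, 5L)
})
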
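tb <- residueTable()

test_that("mass discretization rounds to the nearest index", {
    expect_identical(discretizeMass(111.2, 0.1), 1112L)
    expect_identical(discretizeMass(0), 0L)
    expect_identical(discretizeMass(1234.567, 0.1), 12346L)
    expect_error(discretizeMass(-1))
})

test_that("the forward pass reconstructs a tiled chain from complete PRMs", {
    set.seed(31)
    fx <- makeTilingFixture(L = 40L, nPep = 8L)
    fms <- fullLadderFMS(fx$truth)
    g <- buildOverlapGraph(fx$peptides, accumulate = TRUE)
    out <- forwardPass(g, fx$startIds, fms, fx$chainMass,
                       endIds = fx$endIds)
    expect_gt(length(out), 0L)
    expect_equal(out[[1]]$sequence, fx$truth)
    expect_equal(out[[1]]$T, 39L)
    expect_true(out[[1]]$endOk)

    # a target mass nothing can reach yields no candidates
    none <- forwardPass(g, fx$startIds, fms, fx$chainMass + 500,
                        endIds = fx$endIds)
    expect_length(none, 0L)

    # empty start set raises the typed condition
    expect_error(forwardPass(g, integer(0), fms, fx$chainMass),
                 class = "abseqms_no_start")
})

test_that("the reverse pass mirrors the forward pass", {
    set.seed(33)
    fx <- makeTilingFixture(L = 36L, nPep = 8L)
    fms <- fullLadderFMS(fx$truth)
    g <- buildOverlapGraph(fx$peptides, accumulate = TRUE)
    out <- reversePass(g, fx$endIds, fms, fx$chainMass,
                       startIds = fx$startIds)
    expect_gt(length(out), 0L)
    expect_equal(out[[1]]$sequence, fx$truth)

    # with an empty fragment list scores reduce to the confidence terms
    noFrag <- fragmentMassSet(fx$chainMass, numeric(0))
    out2 <- reversePass(g, fx$endIds, noFrag, fx$chainMass,
                        startIds = fx$startIds)
    expect_true(all(vapply(out2, `[[`, numeric(1), "T") == 0))
})

test_that("DP top-1 equals the exhaustive oracle and capacity is monotone", {
    set.seed(37)
    for (rep in 1:25) {
        fx <- makeTilingFixture(L = sample(28:40, 1), nPep = sample(6:10, 1))
        # partial noisy ladders make scores non-trivial
        full <- fullLadderFMS(fx$truth)
        keep <- sort(sample(fragmentMasses(full),
                            round(0.7 * length(fragmentMasses(full)))))
        fms <- fragmentMassSet(fx$chainMass,
                               keep * (1 + rnorm(length(keep)) * 5e-6))
        g <- buildOverlapGraph(fx$peptides, accumulate = TRUE)
        if (length(fx$startIds) == 0) next
        big <- forwardPass(g, fx$startIds, fms, fx$chainMass,
                           capacity = 64L, endIds = fx$endIds)
        oracle <- oracleBestScore(g, fx$startIds, fx$endIds, prmList(fms),
                                  fms@tolerancePpm, fx$chainMass)
        if (length(big) == 0L) {
            expect_identical(oracle, -Inf)
        } else {
            expect_equal(big[[1]]$finalScore, oracle, tolerance = 1e-9)
        }
        # a larger queue can only help the top score
        small <- forwardPass(g, fx$startIds, fms, fx$chainMass,
                             capacity = 1L, endIds = fx$endIds)
        if (length(small) > 0L && length(big) > 0L)
            expect_gte(big[[1]]$finalScore + 1e-9, small[[1]]$finalScore)
    }
})

test_that("directional merge recovers the truth and rejects bad junctions", {
    set.seed(39)
    fx <- makeTilingFixture(L = 40L, nPep = 10L)
    fms <- fullLadderFMS(fx$truth)
    g <- buildOverlapGraph(fx$peptides, accumulate = TRUE)
    fwd <- forwardPass(g, fx$startIds, fms, fx$chainMass, endIds = fx$endIds)
    rev <- reversePass(g, fx$endIds, fms, fx$chainMass,
                       startIds = fx$startIds)
    psm <- vapply(fx$peptides@residueMass, sum, numeric(1))
    mg <- mergeDirections(fwd, rev, fms, fx$chainMass, psm)
    expect_gt(length(mg), 0L)
    expect_equal(mg[[1]]$sequence, fx$truth)
    expect_equal(sum(mg[[1]]$mass) + tb$constants[["waterMono"]],
                 fx$chainMass, tolerance = 1e-6)

    # a 10 Da target shift voids every merge
    mg2 <- mergeDirections(fwd, rev, fms, fx$chainMass + 10, psm)
    expect_length(mg2, 0L)

    # candidates with disjoint peptide sets cannot merge
    f1 <- fwd[[1]]; r1 <- rev[[1]]
    r1$peptides <- max(f1$peptides) + seq_along(r1$peptides)
    expect_length(mergeDirections(list(f1), list(r1), fms, fx$chainMass,
                                  c(psm, psm)), 0L)
})

test_that("the end penalty demotes paths ending outside the end set", {
    set.seed(43)
    fx <- makeTilingFixture(L = 32L, nPep = 8L)
    fms <- fullLadderFMS(fx$truth)
    g <- buildOverlapGraph(fx$peptides, accumulate = TRUE)
    out <- forwardPass(g, fx$startIds, fms, fx$chainMass,
                       endIds = fx$endIds, penalty = 5)
    ok <- out[[1]]
    expect_true(ok$endOk)
    expect_equal(ok$finalScore, ok$score)
    # stripping the end set re-applies the penalty to every candidate
    pen <- applyEndPenalty(out, integer(0), penalty = 5)
    expect_true(all(!vapply(pen, `[[`, logical(1), "endOk")))
    expect_equal(pen[[1]]$finalScore, pen[[1]]$score - 5)
    # of two equal-score candidates only the end-labelled one escapes it
    two <- applyEndPenalty(list(ok, ok), c(ok$peptides[length(ok$peptides)]),
                           penalty = 5)
    expect_equal(two[[1]]$finalScore - two[[2]]$finalScore, 0)
})

test_that("subunit sequencing attempts all three types and the right one wins", {
    set.seed(47)
    ch <- generateChains(1, sharedFc = FALSE, pyroGlu = 0)
    bu <- emitBottomUp(ch, depth = 5, errorRate = 0)
    md <- emitMiddleDown(ch, siteCoverage = 0.8, ppmNoise = 5)
    pep <- convertIleToLeu(filterPeptides(bu$peptides))
    g <- buildOverlapGraph(pep, accumulate = TRUE)
    tsets <- terminusSets(classifyTerminus(pep))
    lcMass <- ch$subunits$massMono[ch$subunits$type == "LC"][1]
    fmsList <- aggregatePrecursors(md$runs, ch$subunits$massMono, 50)
    fms <- fmsList[[sprintf("%.4f", lcMass)]]
    res <- sequenceSubunit(g, tsets, fms, lcMass)
    expect_equal(res$type, "LC")
    expect_equal(res$status, "ok")
    truth <- chartr("I", "L", paste(substr(ch$chains[[
        ch$subunits$chain[ch$subunits$type == "LC"][1]]], 1, 1),
        collapse = ""))
    expect_gte(residueAccuracy(chartr("I", "L", gsub("[(][^)]*[)]", "",
        res$winner$sequence)), truth), 0.99)

    # without middle-down data the result is flagged
    res2 <- sequenceSubunit(g, tsets, NULL, lcMass)
    expect_equal(res2$status, "no-middledown")
})

test_that("score decomposition: recomputing s(p) from the realized string matches the DP", {
    set.seed(53)
    fx <- makeTilingFixture(L = 34L, nPep = 8L)
    full <- fullLadderFMS(fx$truth)
    keep <- sort(sample(fragmentMasses(full), 40))
    fms <- fragmentMassSet(fx$chainMass, keep)
    g <- buildOverlapGraph(fx$peptides, accumulate = TRUE)
    out <- forwardPass(g, fx$startIds, fms, fx$chainMass, endIds = fx$endIds)
    for (cand in out) {
        s <- oracleScore(cand$mass, cand$acc, prmList(fms),
                         fms@tolerancePpm)
        expect_equal(cand$score, s, tolerance = 1e-9)
        expect_equal(sum(cand$mass), cand$totalMass, tolerance = 1e-9)
    }
})
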
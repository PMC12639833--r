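tb <- residueTable()

# small constructed chains honouring the IdeS junction motif
mkFd <- function(n = 30) c(strsplit(randomSeq(n - 8), "")[[1]],
                           strsplit("CPAPELLG", "")[[1]])
mkFc2 <- function(n = 30) c(strsplit("GPSVFLFP", "")[[1]],
                            strsplit(randomSeq(n - 8), "")[[1]])

spanningReads <- function(fd, fc2, n = 3L) {
    full <- c(fd, fc2)
    j <- length(fd)
    deNovoPeptideSet(vapply(seq_len(n), function(i)
        chartr("I", "L", paste(full[(j - 6):(j + 7)], collapse = "")),
        character(1)))
}

test_that("heavy-chain pairing applies motif, junction-coverage and mass gates", {
    set.seed(91)
    fd <- mkFd(); fc2 <- mkFc2()
    hcAvg <- peptideMass(paste(c(fd, fc2), collapse = ""), tb,
                         mode = "average")
    reduced <- proteoformSet(hcAvg + 0.5, "average")
    reads <- spanningReads(fd, fc2)
    hp <- pairHeavyChains(list(Fd1 = fd), list(Fc2.1 = fc2), reduced, reads)
    expect_equal(nrow(hp), 1L)
    expect_equal(hp$reducedMass, hcAvg + 0.5)

    # a 10 Da mass offset rejects the combination
    hp2 <- pairHeavyChains(list(Fd1 = fd), list(Fc2.1 = fc2),
                           proteoformSet(hcAvg + 10, "average"), reads)
    expect_equal(nrow(hp2), 0L)

    # an unspanned junction rejects it even at 0 ppm
    other <- deNovoPeptideSet(chartr("I", "L", paste(fd[1:10], collapse = "")))
    hp3 <- pairHeavyChains(list(Fd1 = fd), list(Fc2.1 = fc2),
                           proteoformSet(hcAvg, "average"), other)
    expect_equal(nrow(hp3), 0L)

    # a chain violating the hinge motif never pairs
    badFd <- c(fd[1:(length(fd) - 8)], strsplit("WWWWWWWW", "")[[1]])
    hp4 <- pairHeavyChains(list(Fd1 = badFd), list(Fc2.1 = fc2),
                           reduced, reads)
    expect_equal(nrow(hp4), 0L)
})

test_that("printed pairing arithmetic reproduces: Fd + Fc/2 - water vs reduced mass", {
    # deconvoluted-average-mass arithmetic: 25383.27 + 23791.52 - 18.011
    # against an observed reduced mass of 49156.70 is accepted at 1.6 ppm
    calc <- 25383.27 + 23791.52 - tb$constants[["waterAvg"]]
    expect_lt(abs(calc - 49156.70), 4)
    expect_equal(round(ppmDelta(calc, 49156.70), 1), 1.6)
})

test_that("whole-antibody grouping accepts within 100 ppm and reports ambiguity", {
    set.seed(93)
    fd <- mkFd(); fc2 <- mkFc2()
    lc <- strsplit(randomSeq(25), "")[[1]]
    hcAvg <- peptideMass(paste(c(fd, fc2), collapse = ""), tb, mode = "average")
    lcAvg <- peptideMass(paste(lc, collapse = ""), tb, mode = "average")
    wholeTrue <- 2 * (hcAvg + lcAvg) - 16 * tb$constants[["disulfideLossAvg"]]
    reduced <- proteoformSet(c(hcAvg, lcAvg), "average")
    whole <- proteoformSet(wholeTrue, "average")
    hp <- pairHeavyChains(list(Fd1 = fd), list(Fc2.1 = fc2), reduced,
                          spanningReads(fd, fc2))
    gr <- pairAntibodies(list(LC1 = lc), hp, whole, reduced)
    expect_equal(nrow(gr), 1L)
    expect_lt(abs(gr$wholePpm), 100)

    # bispecific pattern: two LCs with one HC give two mass-checked groups
    lc2 <- strsplit(randomSeq(25), "")[[1]]
    lc2Avg <- peptideMass(paste(lc2, collapse = ""), tb, mode = "average")
    whole3 <- proteoformSet(c(wholeTrue,
                              2 * (hcAvg + lc2Avg) - 16 * tb$constants[["disulfideLossAvg"]],
                              hcAvg + lcAvg + lc2Avg + hcAvg -
                                  16 * tb$constants[["disulfideLossAvg"]]),
                            "average")
    red3 <- proteoformSet(c(hcAvg, lcAvg, lc2Avg), "average")
    gr3 <- pairAntibodies(list(LC1 = lc, LC2 = lc2), hp, whole3, red3)
    # both homodimeric forms are recovered; the mixed form matches the
    # homodimer expectation only within its own tolerance
    expect_gte(nrow(gr3), 2L)
    expect_setequal(unique(gr3$lc), c("LC1", "LC2"))
})

test_that("terminal modifications are annotated by smallest reconciling set", {
    s <- paste0(randomSeq(20), "K")
    mAvg <- peptideMass(s, tb, mode = "average")
    expect_equal(annotateTerminalMods(s, mAvg - 128.095), "LysLoss")
    expect_length(annotateTerminalMods(s, mAvg), 0L)
    q <- paste0("Q", randomSeq(20))
    mq <- peptideMass(q, tb, mode = "average")
    expect_equal(annotateTerminalMods(q, mq - 17.027), "PyroGlu")
    expect_warning(ann <- annotateTerminalMods(q, mq - 300), "no terminal")
    expect_null(ann)
})
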
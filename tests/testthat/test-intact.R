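tb <- residueTable()

test_that("RT-window scan merging sums co-eluting peaks and keeps windows apart", {
    s1 <- centroidScan(10.00, 1000.000, 100)
    s2 <- centroidScan(10.05, 1000.002, 100)
    m <- mergeScans(list(s1, s2), window = 0.1, mzTol = 0.01)
    expect_length(m, 1L)
    expect_equal(m[[1]]$intensity, 200)

    s3 <- centroidScan(10.5, 1000.000, 100)
    m2 <- mergeScans(list(s1, s3), window = 0.1)
    expect_length(m2, 2L)

    expect_length(mergeScans(list()), 0L)

    # merged peak count equals a brute-force (window, m/z-cluster) grouping
    set.seed(61)
    scans <- lapply(seq(10, 10.49, by = 0.01), function(rt)
        centroidScan(rt, sort(runif(20, 800, 1200)), runif(20, 1, 100)))
    m3 <- mergeScans(scans, window = 0.1, mzTol = 0.01)
    oracle <- 0L
    rts <- seq(10, 10.49, by = 0.01)
    for (b in unique(floor(rts / 0.1))) {
        mz <- sort(unlist(lapply(scans[floor(rts / 0.1) == b], `[[`, "mz")))
        oracle <- oracle + sum(diff(mz) > 0.01) + 1L
    }
    expect_equal(sum(lengths(lapply(m3, `[[`, "mz"))), oracle)
})

test_that("charge assignment recovers species from clean envelopes", {
    proton <- tb$constants[["proton"]]
    mkScan <- function(masses, ab, z = 20:30) {
        mz <- unlist(lapply(masses, function(M) (M + z * proton) / z))
        it <- unlist(lapply(ab, function(a) rep(a * 1000, length(z))))
        centroidScan(10, mz, it)
    }
    d <- deconvoluteScan(mkScan(23440, 1), zRange = 15:35)
    expect_equal(nrow(d), 1L)
    expect_lt(abs(d$mass[1] - 23440) / 23440 * 1e6, 20)

    # an isolated single peak has no charge support
    d2 <- deconvoluteScan(centroidScan(10, 1172.5, 100), zRange = 15:35)
    expect_equal(nrow(d2), 0L)

    # two co-eluting species are both recovered, abundance order preserved
    d3 <- deconvoluteScan(mkScan(c(23440, 25380), c(3, 1)), zRange = 15:35)
    expect_equal(nrow(d3), 2L)
    o <- order(-d3$intensity)
    expect_lt(abs(d3$mass[o[1]] - 23440), 1)
    expect_lt(abs(d3$mass[o[2]] - 25380), 1)
})

test_that("feature linking enforces RT continuity and consecutive charges", {
    proton <- tb$constants[["proton"]]
    mk <- function(rt, M, z) {
        mz <- (M + z * proton) / z
        list(rt = rt, result = {
            d <- data.frame(mass = M, intensity = 1000)
            d$charges <- list(data.frame(z = z, mz = mz,
                                         intensity = rep(100, length(z))))
            d
        })
    }
    # present across 10 consecutive merged scans at charges 18:25
    dec <- lapply(1:10, function(i) mk(10 + i * 0.1, 23440, 18:25))
    pf <- linkFeatures(dec)
    expect_equal(nrow(proteoformTable(pf)), 1L)
    expect_equal(proteoformTable(pf)$nFeatures, 8L)

    # a single-scan species fails the continuity requirement
    pf2 <- linkFeatures(list(mk(10, 23440, 18:25)), minScans = 3)
    expect_equal(nrow(proteoformTable(pf2)), 0L)

    # charges {5, 9} fail the consecutive-charge rule
    dec3 <- lapply(1:5, function(i) mk(10 + i * 0.1, 23440, c(5L, 9L)))
    pf3 <- linkFeatures(dec3, minChargeRun = 3)
    expect_equal(nrow(proteoformTable(pf3)), 0L)
})

test_that("simulated envelopes round-trip through the full deconvolution", {
    set.seed(67)
    scans <- emitIntactScans(c(23440, 25380), abundances = c(3, 1),
                             rtCenter = c(9.6, 10.4), charges = 20:30)
    pf <- deconvoluteIntact(scans, zRange = 15:35)
    tbl <- proteoformTable(pf)
    expect_gte(nrow(tbl), 2L)
    for (M in c(23440, 25380))
        expect_true(any(abs(tbl$mass - M) / M * 1e6 < 20))
    # abundance ranking preserved for well-separated species
    i1 <- which.min(abs(tbl$mass - 23440))
    i2 <- which.min(abs(tbl$mass - 25380))
    expect_gt(tbl$abundance[i1], tbl$abundance[i2])
})

test_that("the inclusion list is greedy, non-overlapping and capped per mass", {
    feat <- function(z, mzLo, mzHi, rtLo, rtHi, int)
        data.frame(z = z, mzLo = mzLo, mzHi = mzHi, rtLo = rtLo,
                   rtHi = rtHi, intensity = int, mzApex = (mzLo + mzHi) / 2,
                   rtApex = (rtLo + rtHi) / 2)
    f1 <- do.call(rbind, lapply(1:6, function(k)
        feat(20 + k, 1000 + 10 * k, 1005 + 10 * k, 10, 11, 100 - k)))
    pf <- new("ProteoformSet",
              table = data.frame(mass = 23440, mode = "monoisotopic",
                                 abundance = 1, nFeatures = 6L),
              features = list(f1))
    il <- buildInclusionList(pf, perMass = 4L)
    expect_equal(nrow(il), 4L)
    expect_equal(sort(il$z), 21:24)   # the four most intense

    # a proteoform with two features yields two entries, no padding
    pf2 <- new("ProteoformSet",
               table = data.frame(mass = 25000, mode = "monoisotopic",
                                  abundance = 1, nFeatures = 2L),
               features = list(f1[1:2, ]))
    expect_equal(nrow(buildInclusionList(pf2, perMass = 4L)), 2L)

    # a conflicting feature of a second mass is skipped for the next best
    f2 <- rbind(feat(25, 1010, 1015, 10, 11, 98.5),   # clashes with f1 top
                feat(26, 2000, 2005, 12, 13, 1))
    pf3 <- new("ProteoformSet",
               table = data.frame(mass = c(23440, 25000),
                                  mode = "monoisotopic",
                                  abundance = c(0.6, 0.4),
                                  nFeatures = c(6L, 2L)),
               features = list(f1, f2))
    il3 <- buildInclusionList(pf3, perMass = 4L)
    sel2 <- il3[il3$parentMass == 25000, ]
    expect_equal(nrow(sel2), 1L)
    expect_equal(sel2$z, 26L)
    # the clashing 25-kDa feature (z = 25) was skipped entirely
    expect_false(25L %in% il3$z)
})
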
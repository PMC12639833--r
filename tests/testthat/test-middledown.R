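tb <- residueTable()

test_that("PRM and SRM lists derive from the fragment masses by ion offsets", {
    fms <- fragmentMassSet(23000, c(500, 1200, 900))
    expect_equal(fragmentMasses(fms), c(500, 900, 1200))
    expect_equal(prmList(fms), sort(c(500, 900, 1200) - 17.02655),
                 tolerance = 1e-5)
    expect_equal(srmList(fms), sort(c(500, 900, 1200) - 2.00549),
                 tolerance = 1e-5)
})

test_that("precursors pool by subunit mass and duplicates merge intensity-weighted", {
    # four runs with disjoint fragments of one subunit: union
    runs <- lapply(1:4, function(r)
        data.frame(precursorMass = 23000.01, fragMass = 1000 * r,
                   intensity = 1))
    out <- aggregatePrecursors(runs, 23000, tolerancePpm = 50)
    expect_length(out, 1L)
    expect_equal(fragmentMasses(out[[1]]), c(1000, 2000, 3000, 4000))

    # two runs sharing a fragment within 50 ppm: merged to the
    # intensity-weighted mean
    runs2 <- list(
        data.frame(precursorMass = 23000, fragMass = 1000.000, intensity = 3),
        data.frame(precursorMass = 23000, fragMass = 1000.020, intensity = 1))
    out2 <- aggregatePrecursors(runs2, 23000, tolerancePpm = 50)
    expect_length(fragmentMasses(out2[[1]]), 1L)
    expect_equal(fragmentMasses(out2[[1]]), (1000 * 3 + 1000.02) / 4,
                 tolerance = 1e-6)

    # a precursor matching no subunit mass is skipped with a warning
    runs3 <- list(data.frame(precursorMass = 30000, fragMass = 1000,
                             intensity = 1))
    expect_warning(out3 <- aggregatePrecursors(runs3, c(23440, 25380), 50),
                   "no subunit mass")
    expect_length(out3, 0L)
})

test_that("converting an SRM to a PRM inflates the error by the precursor error", {
    e <- srmToPrmError(23001, 23000, 1000.05, 1000)
    expect_equal(unname(e["srmError"]), 0.05)
    expect_equal(unname(e["convertedPrmError"]), 0.95)
    # with a perfect precursor both errors coincide
    e2 <- srmToPrmError(23000, 23000, 1000.05, 1000)
    expect_equal(unname(e2["srmError"]), unname(e2["convertedPrmError"]))
    # randomized instances against direct arithmetic
    set.seed(7)
    for (i in 1:50) {
        pt <- runif(1, 20000, 26000); po <- pt + rnorm(1)
        st <- runif(1, 500, 5000); so <- st + rnorm(1, 0, 0.1)
        e3 <- srmToPrmError(po, pt, so, st)
        expect_equal(unname(e3["srmError"]), abs(so - st))
        expect_equal(unname(e3["convertedPrmError"]),
                     abs((po - so) - (pt - st)))
    }
})

test_that("match counts and coverage behave on noiseless ladders", {
    s <- "PEPTIDESEQVENCERK"
    fms <- fullLadderFMS(s)
    L <- nchar(s)
    expect_equal(countMatches(s, fms, "forward"), L - 1L)
    expect_equal(countMatches(s, fms, "reverse"), L - 1L)
    expect_equal(mdCoverage(s, fms), 1.0)
    # empty fragment set
    empty <- fragmentMassSet(23000, numeric(0))
    expect_equal(countMatches(s, empty, "forward"), 0L)
    # c-ladder only covers half of the possible (c, z) sites
    p <- parsePeptide(s)
    pref <- cumsum(p$mass)[-L]
    cOnly <- fragmentMassSet(peptideMass(s),
                             pref + tb$constants[["cIonOffset"]])
    expect_equal(mdCoverage(s, cOnly), 0.5)
})

test_that("coverage is monotone under fragment deletion and T drops on substitution", {
    set.seed(11)
    s <- randomSeq(30)
    fms <- fullLadderFMS(s)
    cov <- mdCoverage(s, fms)
    frag <- fragmentMasses(fms)
    for (keep in c(0.8, 0.5, 0.2)) {
        sub <- sort(sample(frag, round(keep * length(frag))))
        fms2 <- fragmentMassSet(precursorMass(fms), sub)
        cov2 <- mdCoverage(s, fms2)
        expect_lte(cov2, cov)
        cov <- cov2
    }
    # single interior substitution strictly decreases T on complete data
    toks <- strsplit(s, "")[[1]]
    pos <- 15L
    toks[pos] <- setdiff(c("G", "W"), toks[pos])[1]
    mut <- paste(toks, collapse = "")
    expect_lt(countMatches(mut, fms, "forward"),
              countMatches(s, fms, "forward"))
})
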
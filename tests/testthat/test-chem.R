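test_that("peptide mass is residues plus water, with modifications", {
    expect_equal(peptideMass(""), 18.010565, tolerance = 1e-6)
    expect_equal(peptideMass("G"), 75.03203, tolerance = 1e-5)
    # brute-force summation oracle over the residue table
    tb <- residueTable()
    for (s in c("SEQVENCE", "PEPTIDE", "QWERTY", "ACDEFGHKLMNPQRSTVWY")) {
        expected <- sum(tb$residues[strsplit(s, "")[[1]]]) +
            tb$constants[["waterMono"]]
        expect_equal(peptideMass(s), expected, tolerance = 1e-9)
    }
    # inline modification deltas are snapped to full precision
    expect_equal(peptideMass("Q(-17.03)SV"),
                 peptideMass("QSV") - 17.02654910, tolerance = 1e-6)
    expect_equal(peptideMass("C(+57.02)"),
                 peptideMass("C") + 57.02146372, tolerance = 1e-6)
    expect_error(peptideMass("SEQB"), class = "abseqms_unknown_residue")
})

test_that("the SEQVENCE/EGGECPEP overlap decomposes into the three known mass blocks", {
    aln <- alignMassBlocks("SEQVENCE", "EGGECPEP")
    expect_equal(aln$blockCount, 3L)
    segs <- lapply(aln$blocks, function(b)
        c(paste(b$a, collapse = ""), paste(b$b, collapse = "")))
    expect_equal(segs[[1]], c("E", "E"))
    expect_equal(segs[[2]], c("N", "GG"))
    expect_equal(segs[[3]], c("CE", "EC"))
    # each block conserves mass exactly
    for (b in aln$blocks)
        expect_equal(sum(parsePeptide(paste(b$a, collapse = ""))$mass),
                     sum(parsePeptide(paste(b$b, collapse = ""))$mass),
                     tolerance = 1e-6)
})

test_that("identical peptides fully self-overlap as single-residue blocks", {
    aln <- alignMassBlocks("PEPTIDE", "PEPTIDE")
    expect_equal(aln$blockCount, 7L)
    expect_equal(aln$aStart, 1L)
    expect_true(all(lengths(lapply(aln$blocks, `[[`, "a")) == 1L))
})

test_that("mass-block alignment agrees with the exhaustive oracle on random pairs", {
    set.seed(41)
    for (rep in 1:250) {
        a <- randomSeq(sample(4:12, 1))
        b <- randomSeq(sample(4:12, 1))
        got <- alignMassBlocks(a, b)
        exp <- oracleAlign(a, b)
        if (is.null(exp)) {
            expect_null(got)
        } else {
            expect_equal(got$aStart, exp$aStart,
                         info = paste(a, b))
            expect_equal(got$blockCount, exp$blockCount,
                         info = paste(a, b))
        }
    }
})

test_that("mass-block alignment is symmetric under sequence reversal", {
    set.seed(42)
    revStr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
    for (rep in 1:60) {
        a <- randomSeq(8); b <- randomSeq(8)
        f <- alignMassBlocks(a, b)
        r <- alignMassBlocks(revStr(b), revStr(a))
        if (is.null(f)) expect_null(r)
        else {
            expect_false(is.null(r))
            expect_equal(f$blockCount, r$blockCount)
        }
    }
})

test_that("ppm deltas reproduce pairing-report arithmetic", {
    expect_equal(round(ppmDelta(25383.27 + 23791.52 - 18.011, 49156.70), 1), 1.6)
    expect_equal(round(ppmDelta(23411.85, 23410.93), 1), 39.3)
    expect_equal(ppmDelta(100, 100), 0)
    expect_error(ppmDelta(100, 0))
    expect_error(ppmDelta(100, -5))
})

test_that("the residue table holds the required constants and isobaric identities", {
    tb <- residueTable()
    expect_true(all(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] %in%
                    names(tb$residues)))
    expect_identical(tb$residues[["I"]], tb$residues[["L"]])
    expect_equal(tb$constants[["waterAvg"]], 18.011)
    expect_gt(tb$constants[["averagineResidueMass"]], 0)
    # elementally exact isobaric pairs used by the block aligner
    expect_equal(tb$residues[["N"]], 2 * tb$residues[["G"]], tolerance = 1e-8)
    expect_equal(tb$residues[["Q"]], tb$residues[["G"]] + tb$residues[["A"]],
                 tolerance = 1e-8)
    expect_equal(tb$residues[["S"]] + tb$residues[["L"]],
                 tb$residues[["T"]] + tb$residues[["V"]], tolerance = 1e-8)
})

test_that("residue table overrides load from plain text", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("name\tmass", "X\t123.456", "MyMod\t-10.5"), f)
    tb <- residueTable(f)
    expect_equal(tb$residues[["X"]], 123.456)
    expect_equal(tb$modifications[["MyMod"]], -10.5)
})
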
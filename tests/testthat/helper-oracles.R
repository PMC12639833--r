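# Independent brute-force oracles and small fixture builders used across
# the suite.  Everything here is deliberately naive: recursion and full
# enumeration instead of the package's DP kernels.

.oracleTable <- residueTable()
.AA20 <- setdiff(names(.oracleTable$residues), "I")   # Leu-space alphabet

randomSeq <- function(n) paste(sample(.AA20, n, replace = TRUE),
                               collapse = "")

# exhaustive mass-block alignment oracle: tries every suffix start of A
# (longest first); for each, enumerates every decomposition into blocks of
# <= 2 residues per side by recursion and returns the one with the most
# blocks.  NULL when nothing decomposes or the maximal decomposable
# overlap has fewer than minBlocks blocks.
oracleAlign <- function(a, b, minBlocks = 1L) {
    ma <- parsePeptide(a)$mass
    mb <- parsePeptide(b)$mass
    enum <- function(ai, bi) {
        # returns max block count completing A[ai..] against B[bi..], or -1
        if (ai > length(ma)) return(0L)
        best <- -1L
        for (la in 1:2) {
            if (ai + la - 1L > length(ma)) break
            for (lb in 1:2) {
                if (bi + lb - 1L > length(mb)) break
                if (abs(sum(ma[ai:(ai + la - 1L)]) -
                        sum(mb[bi:(bi + lb - 1L)])) < 1e-6) {
                    rest <- enum(ai + la, bi + lb)
                    if (rest >= 0L && rest + 1L > best) best <- rest + 1L
                }
            }
        }
        best
    }
    for (ai in seq_along(ma)) {
        nb <- enum(ai, 1L)
        if (nb >= 0L) {
            if (nb < minBlocks) return(NULL)
            return(list(aStart = ai, blockCount = nb))
        }
    }
    NULL
}

# score a realized candidate from scratch: T by looping observed fragments
# against the boundary masses, NU from accumulated confidence, NA from the
# averagine residue mass
oracleScore <- function(resMass, acc, frags, tolPpm, lowConf = 0.5,
                        avg = 111.1254) {
    cm <- cumsum(resMass)
    theo <- cm[-length(cm)]
    T <- 0L
    for (f in frags)
        if (length(theo) > 0 && any(abs(theo - f) <= tolPpm * 1e-6 * theo))
            T <- T + 1L
    T + sum(resMass) / avg - sum(acc < lowConf)
}

# exhaustive DP oracle: enumerate every path from every start peptide over
# the graph's edges, collect paths within massTol of the residue-mass
# target, and return the maximum penalized score (-Inf when none)
oracleBestScore <- function(graph, startIds, endIds, frags, tolPpm,
                            subunitMass, massTol = 4, penalty = 5,
                            lowConf = 0.5) {
    pep <- graphPeptides(graph)
    acc <- accumulatedConfidence(graph)
    ed <- graphEdges(graph)
    target <- subunitMass - unname(.oracleTable$constants["waterMono"])
    best <- -Inf
    walk <- function(pid, resMass, accV) {
        m <- sum(resMass)
        if (m > target + massTol) return(invisible())
        if (abs(m - target) <= massTol) {
            s <- oracleScore(resMass, accV, frags, tolPpm, lowConf)
            s <- s - if (pid %in% endIds) 0 else penalty
            if (s > best) best <<- s
        }
        out <- ed[ed$from == pid, , drop = FALSE]
        for (k in seq_len(nrow(out))) {
            v <- out$to[k]
            idx <- seq.int(out$bConsumed[k] + 1L,
                           length(pep@residueMass[[v]]))
            walk(v, c(resMass, pep@residueMass[[v]][idx]),
                 c(accV, acc[[v]][idx]))
        }
    }
    for (s0 in startIds)
        walk(s0, pep@residueMass[[s0]], acc[[s0]])
    best
}

# random tiling fixture: a truth sequence cut into overlapping windows
# forming a guaranteed chain (every consecutive pair overlaps by at least
# three residues) plus a few extra random windows; returns the peptide set
# with start/end ids
makeTilingFixture <- function(L = 40L, nPep = 8L, lenRange = c(8L, 14L)) {
    truth <- randomSeq(L)
    toks <- strsplit(truth, "")[[1]]
    pos <- integer(0); ends <- integer(0)
    s <- 1L
    repeat {
        len <- sample(lenRange[1]:lenRange[2], 1L)
        e <- min(s + len - 1L, L)
        if (L - e < 4L) e <- L
        pos <- c(pos, s); ends <- c(ends, e)
        if (e >= L) break
        # next window starts inside the current one, overlapping >= 3
        s <- sample(seq.int(s + 2L, e - 2L), 1L)
    }
    nExtra <- max(0L, nPep - length(pos))
    for (k in seq_len(nExtra)) {
        s2 <- sample.int(max(1L, L - lenRange[1]), 1L)
        e2 <- min(s2 + sample(lenRange[1]:lenRange[2], 1L) - 1L, L)
        pos <- c(pos, s2); ends <- c(ends, e2)
    }
    seqs <- vapply(seq_along(pos), function(i)
        paste(toks[pos[i]:ends[i]], collapse = ""), character(1))
    list(truth = truth,
         peptides = deNovoPeptideSet(seqs),
         startIds = which(pos == 1L),
         endIds = which(ends == L),
         chainMass = peptideMass(truth))
}

# complete noiseless c/z fragment ladders for a sequence
fullLadderFMS <- function(x, tolPpm = 50, table = .oracleTable) {
    p <- parsePeptide(x, table)
    L <- length(p$mass)
    pref <- cumsum(p$mass)[-L]
    suff <- cumsum(rev(p$mass))[-L]
    fragmentMassSet(peptideMass(p, table),
                    c(pref + table$constants[["cIonOffset"]],
                      suff + table$constants[["zIonOffset"]]),
                    tolerancePpm = tolPpm, table = table)
}
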
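## Synthetic-data generator: ground-truth antibody mixtures and all three
## MS data layers (bottom-up de novo reads, middle-down fragment mass
## lists, intact proteoform masses), with truth labels emitted alongside so
## every downstream module is testable without instrument data.

.LC_STARTS <- c("DIQMTQSP", "EIVLTQSP", "QSVLTQPP")
.FD_STARTS <- c("EVQLVESG", "QVQLVQSG")

.AA_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 2.4, Q = 3.9,
              E = 6.6, G = 7.2, H = 2.2, I = 5.3, L = 9.1, K = 5.8,
              M = 2.2, F = 3.9, P = 4.7, S = 6.6, T = 5.4, W = 1.3,
              Y = 3.3, V = 6.9)

.readTemplates <- function() {
    f <- system.file("extdata", "chain_templates_synthetic.fasta",
                     package = "AbSeqMS", mustWork = TRUE)
    lines <- readLines(f)
    hdr <- grep("^>", lines)
    nm <- sub("^>(\\S+).*", "\\1", lines[hdr])
    to <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i)
        paste(lines[(hdr[i] + 1L):to[i]], collapse = ""), character(1))
    names(seqs) <- nm
    seqs
}

.randomResidues <- function(n)
    sample(names(.AA_FREQ), n, replace = TRUE, prob = .AA_FREQ)

#' Simulation scenario
#'
#' Collects all generator conditions: mixture composition, peptide tiling,
#' confidence and error models, middle-down site coverage and mass noise,
#' and intact mass error.  The defaults are the package's reference study
#' conditions: four antibodies at 3:2:1:1 with pairwise-shared Fc halves,
#' 8x peptide tiling, 2 percent injected isobaric read errors, 60 percent
#' middle-down site coverage at 20 ppm fragment noise.
#'
#' @param nAntibodies number of antibodies in the mixture
#' @param sharedFc two antibodies share one Fc/2 sequence (pairwise)
#' @param bispecific antibody 2 reuses antibody 1's heavy chain, yielding a
#'   2-LC / 1-HC hybridoma-like pattern
#' @param abundances mixture ratios (recycled to \code{nAntibodies})
#' @param depth peptide tiling depth (independent digest passes per chain)
#' @param peptideLen min/max peptide length
#' @param errorRate fraction of reads carrying one injected isobaric error
#' @param etdFraction fraction of reads acquired in EThcD mode
#' @param wIonCoverage probability an EThcD read carries w-ion evidence at
#'   an I/L residue
#' @param siteCoverage marginal middle-down fragmentation-site coverage
#' @param ppmNoise middle-down fragment mass noise (ppm, 1 s.d.)
#' @param decoyRate decoy fragment masses as a fraction of true fragments
#' @param nRuns targeted middle-down runs the fragments are split across
#' @param subunitPpm,reducedPpm,wholePpm intact mass error (ppm, 1 s.d.)
#' @param pyroGlu index of the antibody carrying N-terminal pyroglutamate
#'   (from Gln) on LC and Fd, or 0 for none
#' @param seed random seed; the seed fully determines the dataset
#' @return list of class \code{SimScenario}
#' @export
simScenario <- function(nAntibodies = 4L, sharedFc = TRUE,
                        bispecific = FALSE, abundances = c(3, 2, 1, 1),
                        depth = 8L, peptideLen = c(8L, 20L),
                        errorRate = 0.02, etdFraction = 0.5,
                        wIonCoverage = 0.8, siteCoverage = 0.6,
                        ppmNoise = 20, decoyRate = 0.05, nRuns = 4L,
                        subunitPpm = 10, reducedPpm = 10, wholePpm = 30,
                        pyroGlu = if (nAntibodies >= 2L) nAntibodies else 0L,
                        seed = 1L) {
    structure(as.list(environment()), class = "SimScenario")
}

#' Generate ground-truth antibody chains
#'
#' Variable regions are randomized over residue frequencies behind
#' conserved terminal motifs matching the shipped terminus classifier
#' profiles; constant regions come from synthetic templates.  With
#' \code{sharedFc} the antibodies share Fc/2 sequences pairwise (as
#' co-mixed IgGs of one subclass do); \code{bispecific} makes antibody 2
#' reuse antibody 1's heavy chain.  The pyroglutamate antibody's LC and Fd
#' start with Gln bearing a -17.027 Da delta; all Fc/2 chains lack the
#' C-terminal Lys (the processed molecular forms are simulated).
#'
#' @param nAntibodies,sharedFc,bispecific,pyroGlu see \code{\link{simScenario}}
#' @param seed optional seed (set for standalone use; \code{\link{simulateDataset}}
#'   manages seeding itself)
#' @return list with \code{antibodies} (data.frame: antibody, lc, fd, fc2,
#'   hc), \code{chains} (named list of residue token vectors for every
#'   distinct LC, Fd, Fc/2 and HC), and \code{subunits} (data.frame of the
#'   distinct subunit chains with monoisotopic and average masses)
#' @export
generateChains <- function(nAntibodies = 4L, sharedFc = TRUE,
                           bispecific = FALSE,
                           pyroGlu = if (nAntibodies >= 2L) nAntibodies else 0L,
                           seed = NULL) {
    stopifnot(nAntibodies >= 1L)
    if (!is.null(seed)) set.seed(seed)
    tpl <- .readTemplates()
    tb <- residueTable()
    splitChars <- function(s) strsplit(s, "")[[1]]

    nFc <- if (sharedFc) max(1L, ceiling(nAntibodies / 2)) else nAntibodies
    fcGroup <- if (sharedFc) ceiling(seq_len(nAntibodies) / 2) else
        seq_len(nAntibodies)
    fc2 <- vector("list", nFc)
    base <- splitChars(tpl[["FC2_SYNTH"]])
    for (g in seq_len(nFc)) {
        v <- base
        if (g > 1L) {    # a few allotype-like substitutions per Fc group
            pos <- sample(20:190, 4L)
            v[pos] <- .randomResidues(4L)
        }
        fc2[[g]] <- v
    }

    lc <- fd <- vector("list", nAntibodies)
    for (i in seq_len(nAntibodies)) {
        lcMotif <- if (pyroGlu == i) "QSVLTQPP" else
            .LC_STARTS[((i - 1L) %% 2L) + 1L]
        fdMotif <- if (pyroGlu == i) "QVQLVQSG" else
            .FD_STARTS[((i - 1L) %% 2L) + 1L]
        lc[[i]] <- c(splitChars(lcMotif), .randomResidues(99L),
                     splitChars(tpl[["CL_SYNTH"]]))
        fd[[i]] <- c(splitChars(fdMotif), .randomResidues(114L),
                     splitChars(tpl[["CH1_SYNTH"]]))
        if (pyroGlu == i) {
            lc[[i]][1] <- "Q(-17.03)"
            fd[[i]][1] <- "Q(-17.03)"
        }
    }
    if (bispecific && nAntibodies >= 2L) {
        fd[[2]] <- fd[[1]]
        fcGroup[2] <- fcGroup[1]
    }

    ab <- data.frame(antibody = seq_len(nAntibodies),
                     lc = sprintf("LC%d", seq_len(nAntibodies)),
                     fd = sprintf("Fd%d", seq_len(nAntibodies)),
                     fc2 = sprintf("Fc2.%d", fcGroup),
                     hc = sprintf("HC%d", seq_len(nAntibodies)),
                     stringsAsFactors = FALSE)
    if (bispecific && nAntibodies >= 2L) {
        ab$fd[2] <- ab$fd[1]; ab$hc[2] <- ab$hc[1]
    }

    chains <- list()
    for (i in seq_len(nAntibodies)) {
        chains[[ab$lc[i]]] <- lc[[i]]
        chains[[ab$fd[i]]] <- fd[[i]]
        chains[[ab$hc[i]]] <- c(fd[[i]], fc2[[fcGroup[i]]])
    }
    for (g in seq_len(nFc)) chains[[sprintf("Fc2.%d", g)]] <- fc2[[g]]

    subIds <- unique(c(ab$lc, ab$fd, ab$fc2))
    subType <- ifelse(grepl("^LC", subIds), "LC",
                      ifelse(grepl("^Fd", subIds), "Fd", "Fc2"))
    subunits <- data.frame(
        chain = subIds, type = subType,
        length = vapply(chains[subIds], length, integer(1)),
        massMono = vapply(chains[subIds], function(x)
            peptideMass(paste(x, collapse = ""), tb), numeric(1)),
        massAvg = vapply(chains[subIds], function(x)
            peptideMass(paste(x, collapse = ""), tb, mode = "average"),
            numeric(1)),
        stringsAsFactors = FALSE)
    list(antibodies = ab, chains = chains, subunits = subunits)
}

# internal fast constructor (token lists already parsed)
.peptideSetFromTokens <- function(residues, residueMass, confidence,
                                  mode, spectrumId = NULL, wIon = NULL,
                                  alc = NULL) {
    n <- length(residues)
    if (is.null(spectrumId)) spectrumId <- sprintf("S%06d", seq_len(n))
    if (is.null(wIon)) wIon <- lapply(residues, function(r) rep("", length(r)))
    if (is.null(alc)) alc <- vapply(confidence, mean, numeric(1))
    new("DeNovoPeptideSet",
        sequence = vapply(residues, paste, character(1), collapse = ""),
        residues = residues, residueMass = residueMass,
        confidence = confidence, alc = alc, mode = mode,
        spectrumId = spectrumId, wIon = wIon)
}

# one isobaric read error at a random interior site; returns NULL or
# list(tokens, mass, pos, len, orig, repl)
.injectIsobaric <- function(tokens, mass, table) {
    L <- length(tokens)
    if (L < 6L) return(NULL)
    letters <- substr(tokens, 1L, 1L)
    interior <- 2:(L - 1L)
    cand <- list()
    for (p in interior) {
        le <- letters[p]
        if (le == "N") cand[[length(cand) + 1L]] <- list(p = p, len = 1L, repl = c("G", "G"))
        if (le == "Q") cand[[length(cand) + 1L]] <- list(p = p, len = 1L, repl = c("G", "A"))
        if (p < L - 1L) {
            le2 <- letters[p + 1L]
            if (le == "G" && le2 == "G") cand[[length(cand) + 1L]] <- list(p = p, len = 2L, repl = "N")
            if (le == "G" && le2 == "A") cand[[length(cand) + 1L]] <- list(p = p, len = 2L, repl = "Q")
            if (le == "S" && le2 == "L") cand[[length(cand) + 1L]] <- list(p = p, len = 2L, repl = c("T", "V"))
            if (le == "T" && le2 == "V") cand[[length(cand) + 1L]] <- list(p = p, len = 2L, repl = c("S", "L"))
            if (le != le2 && !grepl("\\(", tokens[p]) && !grepl("\\(", tokens[p + 1L]))
                cand[[length(cand) + 1L]] <- list(p = p, len = 2L, repl = c(le2, le))
        }
    }
    if (length(cand) == 0L) return(NULL)
    ch <- cand[[sample.int(length(cand), 1L)]]
    orig <- tokens[ch$p:(ch$p + ch$len - 1L)]
    newTok <- c(tokens[seq_len(ch$p - 1L)], ch$repl,
                if (ch$p + ch$len <= L) tokens[(ch$p + ch$len):L])
    newMass <- c(mass[seq_len(ch$p - 1L)],
                 unname(table$residues[ch$repl]),
                 if (ch$p + ch$len <= L) mass[(ch$p + ch$len):L])
    list(tokens = newTok, mass = newMass, pos = ch$p,
         len = length(ch$repl), orig = paste(orig, collapse = ""),
         repl = paste(ch$repl, collapse = ""))
}

#' Emit bottom-up de novo reads
#'
#' Tiles every distinct molecular species (LC, HC, Fd, Fc/2) with
#' \code{depth} independent digest passes of randomly cut 8-20 residue
#' windows; every pass starts at the chain N terminus and ends at the C
#' terminus, so reads terminating at both chain and subunit boundaries
#' exist.  Local confidence is drawn Beta(9, 1.5) in the read interior and
#' Beta(3, 2) at the two terminal residues of each read (poor terminal
#' fragmentation); injected isobaric errors (rate \code{errorRate}) carry
#' clearly low confidence at the error site and its neighbours.  Reads are
#' emitted in Leu-space; EThcD reads carry per-residue w-ion evidence of
#' the true I/L identity at \code{wIonCoverage}.
#'
#' @param chainSet output of \code{\link{generateChains}}
#' @param depth,peptideLen,errorRate,etdFraction,wIonCoverage see
#'   \code{\link{simScenario}}
#' @param seed optional seed
#' @param table a \code{\link{residueTable}}
#' @return list with \code{peptides} (a \linkS4class{DeNovoPeptideSet}),
#'   \code{truth} (read provenance and terminus-class labels) and
#'   \code{errors} (injected-error log)
#' @export
emitBottomUp <- function(chainSet, depth = 8L, peptideLen = c(8L, 20L),
                         errorRate = 0.02, etdFraction = 0.5,
                         wIonCoverage = 0.8, seed = NULL,
                         table = residueTable()) {
    if (!is.null(seed)) set.seed(seed)
    chains <- chainSet$chains
    ab <- chainSet$antibodies
    fdLen <- vapply(chains[unique(ab$fd)], length, integer(1))
    resid <- massL <- confL <- wIonL <- list()
    mode <- character(0)
    truth <- list(); errors <- list()
    rid <- 0L
    for (cid in names(chains)) {
        toks <- chains[[cid]]
        ms <- tokenMasses(toks, table)
        L <- length(toks)
        type <- if (grepl("^LC", cid)) "LC" else if (grepl("^Fd", cid)) "Fd"
                else if (grepl("^Fc2", cid)) "Fc2" else "HC"
        jFd <- if (type == "HC") fdLen[[ab$fd[match(cid, ab$hc)]]] else NA_integer_
        for (pass in seq_len(depth)) {
            pos <- 1L
            while (pos <= L) {
                len <- sample(peptideLen[1]:peptideLen[2], 1L)
                end <- min(pos + len - 1L, L)
                if (L - end < peptideLen[1] && end < L) end <- L
                tk <- toks[pos:end]; mk <- ms[pos:end]
                n <- length(tk)
                conf <- stats::rbeta(n, 9, 1.5)
                edge <- unique(c(1:min(2L, n), (n - 1L):n))
                edge <- edge[edge >= 1L & edge <= n]
                conf[edge] <- stats::rbeta(length(edge), 3, 2)
                err <- NULL
                if (stats::runif(1) < errorRate) {
                    err <- .injectIsobaric(tk, mk, table)
                    if (!is.null(err)) {
                        tk <- err$tokens; mk <- err$mass
                        n <- length(tk)
                        conf <- conf[seq_len(n)]
                        if (anyNA(conf)) conf[is.na(conf)] <- stats::rbeta(sum(is.na(conf)), 9, 1.5)
                        ep <- err$pos:(err$pos + err$len - 1L)
                        conf[ep] <- stats::runif(length(ep), 0.10, 0.45)
                        nb <- c(err$pos - 1L, err$pos + err$len)
                        nb <- nb[nb >= 1L & nb <= n]
                        conf[nb] <- stats::runif(length(nb), 0.15, 0.49)
                    }
                }
                md <- if (stats::runif(1) < etdFraction) "EThcD" else "HCD"
                letters <- substr(tk, 1L, 1L)
                wi <- rep("", n)
                if (md == "EThcD") {
                    il <- which(letters %in% c("I", "L"))
                    ev <- il[stats::runif(length(il)) < wIonCoverage]
                    wi[ev] <- letters[ev]
                }
                isI <- letters == "I"
                if (any(isI)) tk[isI] <- sub("^I", "L", tk[isI])
                rid <- rid + 1L
                resid[[rid]] <- tk; massL[[rid]] <- mk
                confL[[rid]] <- conf; wIonL[[rid]] <- wi
                mode[rid] <- md
                lab <- "OTHER"
                if (pos == 1L) lab <- switch(type, LC = "LC-START",
                    Fd = "Fd-START", Fc2 = "Fc/2-START", HC = "Fd-START")
                else if (end == L) lab <- switch(type, LC = "LC-END",
                    Fd = "Fd-END", Fc2 = "Fc/2-END", HC = "Fc/2-END")
                else if (type == "HC" && !is.na(jFd)) {
                    if (end == jFd) lab <- "Fd-END"
                    if (pos == jFd + 1L) lab <- "Fc/2-START"
                }
                truth[[rid]] <- data.frame(read = rid, chain = cid,
                    start = pos, end = end, pass = pass, label = lab,
                    hasError = !is.null(err), stringsAsFactors = FALSE)
                if (!is.null(err))
                    errors[[length(errors) + 1L]] <- data.frame(
                        read = rid, chain = cid, chainPos = pos + err$pos - 1L,
                        orig = err$orig, repl = err$repl,
                        stringsAsFactors = FALSE)
                pos <- end + 1L
            }
        }
    }
    list(peptides = .peptideSetFromTokens(resid, massL, confL, mode,
                                          wIon = wIonL),
         truth = do.call(rbind, truth),
         errors = if (length(errors)) do.call(rbind, errors) else
             data.frame(read = integer(0)))
}

#' Emit middle-down fragment mass lists
#'
#' For every distinct subunit chain, c-ion fragmentation sites are retained
#' with probability biased towards the N-terminal half (and z sites towards
#' the C-terminal half, mirroring where ETD fragments of ~25 kDa subunits
#' are observed), with marginal retention \code{siteCoverage}.  Neutral
#' fragment masses (prefix + c offset, suffix + z offset) receive Gaussian
#' ppm noise and are split across \code{nRuns} emulated targeted runs, each
#' carrying its own slightly perturbed precursor mass; decoy masses are
#' added at \code{decoyRate}.
#'
#' @param chainSet output of \code{\link{generateChains}}
#' @param siteCoverage,ppmNoise,decoyRate,nRuns see \code{\link{simScenario}}
#' @param seed optional seed
#' @param table a \code{\link{residueTable}}
#' @return list with \code{runs} (per-run data.frames: precursorMass,
#'   fragMass, intensity) and \code{truth} (planted c/z sites per subunit)
#' @export
emitMiddleDown <- function(chainSet, siteCoverage = 0.6, ppmNoise = 20,
                           decoyRate = 0.05, nRuns = 4L, seed = NULL,
                           table = residueTable()) {
    stopifnot(siteCoverage >= 0, siteCoverage <= 1)
    if (!is.null(seed)) set.seed(seed)
    cOff <- unname(table$constants["cIonOffset"])
    zOff <- unname(table$constants["zIonOffset"])
    runs <- lapply(seq_len(nRuns), function(i)
        data.frame(precursorMass = numeric(0), fragMass = numeric(0),
                   intensity = numeric(0)))
    truth <- list()
    for (k in seq_len(nrow(chainSet$subunits))) {
        cid <- chainSet$subunits$chain[k]
        toks <- chainSet$chains[[cid]]
        ms <- tokenMasses(toks, table)
        L <- length(ms)
        pref <- cumsum(ms)[-L]
        suff <- cumsum(rev(ms))[-L]
        site <- seq_len(L - 1L)
        pC <- pmin(0.98, ifelse(site <= L / 2, 1.5, 0.5) * siteCoverage)
        pZ <- rev(pC)
        cKeep <- stats::runif(L - 1L) < pC
        zKeep <- stats::runif(L - 1L) < pZ
        frag <- c(pref[cKeep] + cOff, suff[zKeep] + zOff)
        nDecoy <- round(decoyRate * length(frag))
        if (nDecoy > 0)
            frag <- c(frag, stats::runif(nDecoy, 800,
                                         chainSet$subunits$massMono[k] - 800))
        frag <- frag * (1 + stats::rnorm(length(frag)) * ppmNoise * 1e-6)
        inten <- stats::rlnorm(length(frag), 10, 1)
        run1 <- sample.int(nRuns, length(frag), replace = TRUE)
        precTrue <- chainSet$subunits$massMono[k]
        for (r in seq_len(nRuns)) {
            sel <- run1 == r
            dup <- which(!sel & stats::runif(length(frag)) < 0.25)
            idx <- c(which(sel), dup)
            if (length(idx) == 0L) next
            prec <- precTrue * (1 + stats::rnorm(1) * 2e-6)
            runs[[r]] <- rbind(runs[[r]], data.frame(
                precursorMass = prec, fragMass = frag[idx],
                intensity = inten[idx]))
        }
        truth[[cid]] <- list(cSites = which(cKeep), zSites = which(zKeep),
                             nDecoy = nDecoy)
    }
    list(runs = runs, truth = truth)
}

#' Construct a ProteoformSet from plain mass lists
#'
#' @param mass neutral masses (Da)
#' @param mode mass mode per entry (\code{"monoisotopic"}/\code{"average"})
#' @param abundance relative abundances (normalized to sum 1)
#' @param features optional per-mass feature data.frames
#' @return a \linkS4class{ProteoformSet}
#' @export
proteoformSet <- function(mass, mode = "monoisotopic",
                          abundance = rep(1, length(mass)),
                          features = NULL) {
    if (length(mode) == 1L) mode <- rep(mode, length(mass))
    if (is.null(features))
        features <- replicate(length(mass),
            data.frame(z = integer(0), mzLo = numeric(0), mzHi = numeric(0),
                       rtLo = numeric(0), rtHi = numeric(0),
                       intensity = numeric(0), mzApex = numeric(0),
                       rtApex = numeric(0)), simplify = FALSE)
    ab <- if (sum(abundance) > 0) abundance / sum(abundance) else abundance
    new("ProteoformSet",
        table = data.frame(mass = mass, mode = mode, abundance = ab,
                           nFeatures = vapply(features, nrow, integer(1))),
        features = features)
}

#' Emit intact proteoform mass lists
#'
#' Pre-deconvoluted proteoform masses for the three intact samples:
#' subunit (monoisotopic), reduced LC/HC (average) and whole antibody
#' (average; twice HC plus LC minus 16 disulfide bonds), each with Gaussian
#' ppm error and abundances following the mixture ratios.
#'
#' @param chainSet output of \code{\link{generateChains}}
#' @param abundances mixture ratios
#' @param subunitPpm,reducedPpm,wholePpm mass error (ppm, 1 s.d.)
#' @param disulfides disulfide bonds per whole antibody (default 16)
#' @param seed optional seed
#' @param table a \code{\link{residueTable}}
#' @return list of \linkS4class{ProteoformSet}: \code{subunit},
#'   \code{reduced}, \code{whole}, plus \code{truth} (exact masses)
#' @export
emitIntact <- function(chainSet, abundances = c(3, 2, 1, 1),
                       subunitPpm = 10, reducedPpm = 10, wholePpm = 30,
                       disulfides = 16L, seed = NULL,
                       table = residueTable()) {
    if (!is.null(seed)) set.seed(seed)
    ab <- chainSet$antibodies
    abd <- rep_len(abundances, nrow(ab))
    noisy <- function(m, ppm) m * (1 + stats::rnorm(length(m)) * ppm * 1e-6)

    subAb <- vapply(chainSet$subunits$chain, function(cid)
        sum(abd[ab$lc == cid | ab$fd == cid | ab$fc2 == cid]), numeric(1))
    subunit <- proteoformSet(noisy(chainSet$subunits$massMono, subunitPpm),
                             "monoisotopic", subAb)

    lcIds <- unique(ab$lc); hcIds <- unique(ab$hc)
    redIds <- c(lcIds, hcIds)
    redTrue <- vapply(chainSet$chains[redIds], function(x)
        peptideMass(paste(x, collapse = ""), table, mode = "average"),
        numeric(1))
    redAb <- vapply(redIds, function(cid)
        sum(abd[ab$lc == cid | ab$hc == cid]), numeric(1))
    reduced <- proteoformSet(noisy(redTrue, reducedPpm), "average", redAb)

    ssLoss <- disulfides * unname(table$constants["disulfideLossAvg"])
    wholeTrue <- vapply(seq_len(nrow(ab)), function(i)
        2 * (redTrue[[ab$hc[i]]] + redTrue[[ab$lc[i]]]) - ssLoss, numeric(1))
    whole <- proteoformSet(noisy(wholeTrue, wholePpm), "average", abd)

    list(subunit = subunit, reduced = reduced, whole = whole,
         truth = list(subunitMass = chainSet$subunits$massMono,
                      reducedMass = redTrue, wholeMass = wholeTrue,
                      reducedIds = redIds))
}

#' Synthesize intact centroid scans for one co-eluting species set
#'
#' Charge-envelope synthesis for exercising the intact deconvolution end to
#' end: each species elutes as a Gaussian over RT and appears as one
#' centroid peak per charge at (M + z p)/z with multiplicative m/z noise.
#'
#' @param masses neutral species masses (Da)
#' @param abundances relative intensities
#' @param charges charge range of the envelope
#' @param rtCenter,rtSigma elution apex (min) and width per species
#' @param scanInterval scan spacing (min)
#' @param rtRange total RT span (min)
#' @param mzNoisePpm centroid m/z noise (ppm, 1 s.d.)
#' @param seed optional seed
#' @param table a \code{\link{residueTable}}
#' @return list of \code{\link{centroidScan}}
#' @export
emitIntactScans <- function(masses, abundances = rep(1, length(masses)),
                            charges = 20:30,
                            rtCenter = rep(10, length(masses)),
                            rtSigma = 0.15, scanInterval = 0.02,
                            rtRange = c(9, 11), mzNoisePpm = 2,
                            seed = NULL, table = residueTable()) {
    if (!is.null(seed)) set.seed(seed)
    proton <- unname(table$constants["proton"])
    rts <- seq(rtRange[1], rtRange[2], by = scanInterval)
    lapply(rts, function(rt) {
        mz <- numeric(0); it <- numeric(0)
        for (s in seq_along(masses)) {
            el <- exp(-((rt - rtCenter[s])^2) / (2 * rtSigma^2))
            if (el < 0.01) next
            # plateau-ish charge envelope so consecutive charges survive
            zw <- stats::dnorm(charges, mean(charges), length(charges) / 2)
            zw <- zw / max(zw)
            m <- (masses[s] + charges * proton) / charges
            m <- m * (1 + stats::rnorm(length(m)) * mzNoisePpm * 1e-6)
            mz <- c(mz, m)
            it <- c(it, 1e6 * abundances[s] * el * zw)
        }
        centroidScan(rt, mz, it)
    })
}

#' Simulate a complete dataset
#'
#' Runs \code{\link{generateChains}}, \code{\link{emitBottomUp}},
#' \code{\link{emitMiddleDown}} and \code{\link{emitIntact}} under one seed
#' and returns the input bundle consumed by \code{\link{runPipeline}}
#' together with the full ground truth.
#'
#' @param scenario a \code{\link{simScenario}}
#' @return list with \code{peptides}, \code{mdRuns}, \code{subunit},
#'   \code{reduced}, \code{whole} (pipeline inputs) and \code{truth}
#' @export
simulateDataset <- function(scenario = simScenario()) {
    set.seed(scenario$seed)
    ch <- generateChains(scenario$nAntibodies, scenario$sharedFc,
                         scenario$bispecific, scenario$pyroGlu)
    bu <- emitBottomUp(ch, scenario$depth, scenario$peptideLen,
                       scenario$errorRate, scenario$etdFraction,
                       scenario$wIonCoverage)
    md <- emitMiddleDown(ch, scenario$siteCoverage, scenario$ppmNoise,
                         scenario$decoyRate, scenario$nRuns)
    im <- emitIntact(ch, scenario$abundances, scenario$subunitPpm,
                     scenario$reducedPpm, scenario$wholePpm)
    list(peptides = bu$peptides, mdRuns = md$runs,
         subunit = im$subunit, reduced = im$reduced, whole = im$whole,
         truth = list(chainSet = ch, reads = bu$truth, errors = bu$errors,
                      mdSites = md$truth, intact = im$truth),
         scenario = scenario)
}
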
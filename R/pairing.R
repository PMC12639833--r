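## Antibody pairing from intact masses: Fd + Fc/2 -> heavy chain
## (enzyme-rule and junction-coverage gated, validated against reduced
## masses), then LC + HC -> whole antibody (validated against whole intact
## masses), plus terminal-modification annotation.

.JUNCTION_RULES <- list(
    IdeS = list(fdSuffix = "LLG", fc2Prefix = "G"),
    SpeB = list(fdSuffix = "KTH", fc2Prefix = "T"))

.chainAvgMass <- function(tokens, table)
    peptideMass(paste(tokens, collapse = ""), table, mode = "average")

#' Pair Fd and Fc/2 subunits into heavy chains
#'
#' All Fd x Fc/2 combinations are kept whose junction satisfies the
#' hinge-protease motif (IdeS cleaves after the ...LLG | G... motif; SpeB
#' motifs are configurable), whose junction is spanned by at least one
#' bottom-up read (exact Leu-space match of an 8-mer centred on the
#' junction), and whose combined average mass (Fd + Fc/2 minus water) is
#' within \code{tolDa} of an observed reduced mass.
#'
#' @param fdList named list of Fd residue-token vectors
#' @param fc2List named list of Fc/2 residue-token vectors
#' @param reducedPf reduced-sample \linkS4class{ProteoformSet} (average
#'   masses)
#' @param peptides the filtered \linkS4class{DeNovoPeptideSet}
#' @param enzyme \code{"IdeS"} or \code{"SpeB"}
#' @param junctionRule optional list(fdSuffix, fc2Prefix) overriding the
#'   enzyme motifs
#' @param tolDa reduced-mass tolerance (default 4 Da)
#' @param table a \code{\link{residueTable}}
#' @return data.frame: fd, fc2, hcMass (calculated), reducedMass
#'   (observed), ppm; attribute \code{"hcTokens"} holds the joined chains
#' @export
pairHeavyChains <- function(fdList, fc2List, reducedPf, peptides,
                            enzyme = c("IdeS", "SpeB"),
                            junctionRule = NULL, tolDa = 4,
                            table = residueTable()) {
    enzyme <- match.arg(enzyme)
    rule <- if (is.null(junctionRule)) .JUNCTION_RULES[[enzyme]] else junctionRule
    obs <- proteoformTable(reducedPf)$mass
    pepStr <- vapply(peptides@residues, .lString, character(1))
    rows <- list(); hcTokens <- list()
    for (fi in names(fdList)) for (ci in names(fc2List)) {
        fd <- fdList[[fi]]; fc2 <- fc2List[[ci]]
        fdStr <- .lString(fd); fcStr <- .lString(fc2)
        if (!endsWith(fdStr, chartr("I", "L", rule$fdSuffix))) next
        if (!startsWith(fcStr, chartr("I", "L", rule$fc2Prefix))) next
        j <- length(fd)
        full <- paste0(fdStr, fcStr)
        mer <- substr(full, j - 3L, j + 4L)
        if (nchar(mer) < 8L || !any(grepl(mer, pepStr, fixed = TRUE))) next
        hcMass <- .chainAvgMass(fd, table) + .chainAvgMass(fc2, table) -
            unname(table$constants["waterAvg"])
        d <- abs(obs - hcMass)
        if (length(d) == 0L || min(d) > tolDa) next
        o <- which.min(d)
        rows[[length(rows) + 1L]] <- data.frame(
            fd = fi, fc2 = ci, hcMass = hcMass, reducedMass = obs[o],
            ppm = ppmDelta(hcMass, obs[o]), stringsAsFactors = FALSE)
        hcTokens[[paste(fi, ci, sep = "+")]] <- c(fd, fc2)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(fd = character(0), fc2 = character(0),
                   hcMass = numeric(0), reducedMass = numeric(0),
                   ppm = numeric(0))
    attr(out, "hcTokens") <- hcTokens
    out
}

#' Group light and heavy chains into whole antibodies
#'
#' For every LC x paired-HC combination the expected whole-antibody mass is
#' twice the sum of the observed reduced HC and LC masses minus
#' \code{disulfides} disulfide bonds; combinations within \code{tolPpm} of
#' an observed whole intact mass are reported.  All mass-consistent
#' pairings are returned, including ambiguous ones -- intact mass alone
#' cannot always exclude a false pairing.
#'
#' @param lcList named list of LC residue-token vectors
#' @param hcPairs output of \code{\link{pairHeavyChains}}
#' @param wholePf whole-sample \linkS4class{ProteoformSet} (average masses)
#' @param reducedPf reduced-sample \linkS4class{ProteoformSet}, source of
#'   the observed LC masses
#' @param disulfides disulfide bonds per antibody (default 16)
#' @param tolPpm whole-mass tolerance (default 100 ppm; lenient because
#'   partially reformed disulfide bonds shift reduced masses)
#' @param tolDaLc LC-to-reduced-mass tolerance (default 4 Da)
#' @param table a \code{\link{residueTable}}
#' @return data.frame with one row per antibody group: lc, fd, fc2,
#'   lcMass, lcReduced (ppm), hcMass, hcReduced (ppm), wholeExpected,
#'   wholeObserved, wholePpm
#' @export
pairAntibodies <- function(lcList, hcPairs, wholePf, reducedPf,
                           disulfides = 16L, tolPpm = 100, tolDaLc = 4,
                           table = residueTable()) {
    obsW <- proteoformTable(wholePf)$mass
    obsR <- proteoformTable(reducedPf)$mass
    ssLoss <- disulfides * unname(table$constants["disulfideLossAvg"])
    rows <- list()
    for (li in names(lcList)) {
        lcMass <- .chainAvgMass(lcList[[li]], table)
        d <- abs(obsR - lcMass)
        if (length(d) == 0L || min(d) > tolDaLc) next
        lcObs <- obsR[which.min(d)]
        for (k in seq_len(nrow(hcPairs))) {
            expW <- 2 * (hcPairs$reducedMass[k] + lcObs) - ssLoss
            dw <- abs(ppmDelta(expW, obsW))
            hits <- which(dw <= tolPpm)
            for (h in hits) {
                rows[[length(rows) + 1L]] <- data.frame(
                    lc = li, fd = hcPairs$fd[k], fc2 = hcPairs$fc2[k],
                    lcMass = lcMass, lcReduced = lcObs,
                    lcPpm = ppmDelta(lcMass, lcObs),
                    hcMass = hcPairs$hcMass[k],
                    hcReduced = hcPairs$reducedMass[k],
                    hcPpm = hcPairs$ppm[k],
                    wholeExpected = expW, wholeObserved = obsW[h],
                    wholePpm = ppmDelta(expW, obsW[h]),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(rows)) do.call(rbind, rows) else
        data.frame(lc = character(0), fd = character(0), fc2 = character(0),
                   lcMass = numeric(0), lcReduced = numeric(0),
                   lcPpm = numeric(0), hcMass = numeric(0),
                   hcReduced = numeric(0), hcPpm = numeric(0),
                   wholeExpected = numeric(0), wholeObserved = numeric(0),
                   wholePpm = numeric(0))
}

#' Annotate terminal modifications from an observed mass
#'
#' Finds the smallest combination of terminal modifications (C-terminal
#' Lys truncation, N-terminal pyroglutamate from Gln) reconciling a
#' sequence's calculated mass with an observed intact mass within
#' tolerance.  Lys truncation applies only to sequences ending in K,
#' pyroglutamate only to sequences starting with unmodified Q.
#'
#' @param x sequence (string or token vector)
#' @param observedMass observed mass (Da)
#' @param mode mass mode of the observation
#' @param tolDa tolerance (default 2 Da)
#' @param table a \code{\link{residueTable}}
#' @return character vector of modification names (possibly empty); NULL
#'   with a warning when no combination fits
#' @export
annotateTerminalMods <- function(x, observedMass,
                                 mode = c("average", "monoisotopic"),
                                 tolDa = 2, table = residueTable()) {
    mode <- match.arg(mode)
    if (is.character(x) && length(x) > 1L) x <- paste(x, collapse = "")
    p <- parsePeptide(x, table)
    base <- peptideMass(p, table, mode = mode)
    combos <- list(character(0))
    if (p$letters[length(p$letters)] == "K")
        combos <- c(combos, list("LysLoss"))
    if (p$letters[1] == "Q" && p$tokens[1] == "Q")
        combos <- c(combos, list("PyroGlu"))
    if (length(combos) == 3L)
        combos <- c(combos, list(c("LysLoss", "PyroGlu")))
    err <- vapply(combos, function(cmb)
        abs(base + sum(table$modifications[cmb]) - observedMass), numeric(1))
    ok <- which(err <= tolDa)
    if (length(ok) == 0L) {
        warning("no terminal modification combination reconciles the mass")
        return(NULL)
    }
    sizes <- lengths(combos)[ok]
    ok <- ok[order(sizes, err[ok])]
    combos[[ok[1]]]
}
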
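## Middle-down fragment mass handling: per-subunit aggregation of
## deconvoluted neutral c/z fragment masses, PRM/SRM derivation, fragment
## matching and coverage.  MS2 isotope deconvolution happens upstream; this
## module consumes neutral mass lists.

#' Construct a FragmentMassSet
#'
#' Builds the aggregated middle-down fragment container for one subunit
#' precursor and derives the two directional mass lists: PRMs (every
#' fragment read as a c ion, offset 17.02655 Da) and SRMs (every fragment
#' read as a z ion, offset 2.00549 Da).
#'
#' @param precursorMass neutral monoisotopic subunit mass (Da)
#' @param fragments neutral fragment masses (Da)
#' @param intensity fragment intensities (defaults to 1)
#' @param tolerancePpm match tolerance in ppm (default 50)
#' @param table a \code{\link{residueTable}} supplying the ion offsets
#' @return a \linkS4class{FragmentMassSet}
#' @export
fragmentMassSet <- function(precursorMass, fragments,
                            intensity = rep(1, length(fragments)),
                            tolerancePpm = 50, table = residueTable()) {
    o <- order(fragments)
    fragments <- fragments[o]
    intensity <- intensity[o]
    cOff <- unname(table$constants["cIonOffset"])
    zOff <- unname(table$constants["zIonOffset"])
    prm <- sort(fragments - cOff)
    srm <- sort(fragments - zOff)
    new("FragmentMassSet", precursorMass = precursorMass,
        fragmentMass = fragments, intensity = intensity,
        prm = prm[prm > 0], srm = srm[srm > 0],
        tolerancePpm = tolerancePpm)
}

#' Pool per-run precursor fragment lists by subunit mass
#'
#' Precursors (from the four targeted runs) whose neutral masses agree with
#' the same deconvoluted subunit mass within tolerance are pooled into one
#' fragment mass list; duplicate fragment masses within tolerance are merged
#' into a single entry at the intensity-weighted mean mass with summed
#' intensity.  Precursors matching no subunit mass are skipped with a
#' warning.
#'
#' @param runs list of data.frames with columns \code{precursorMass},
#'   \code{fragMass}, \code{intensity} (one data.frame per LC-MS/MS run)
#' @param subunitMasses numeric vector of deconvoluted subunit masses (Da)
#' @param tolerancePpm precursor-to-subunit and duplicate-merge tolerance
#' @param table a \code{\link{residueTable}}
#' @return named list of \linkS4class{FragmentMassSet}, one per subunit mass
#'   that attracted at least one precursor; names are the subunit masses.
#' @export
aggregatePrecursors <- function(runs, subunitMasses, tolerancePpm = 50,
                                table = residueTable()) {
    stopifnot(length(subunitMasses) > 0)
    pooledF <- vector("list", length(subunitMasses))
    pooledI <- vector("list", length(subunitMasses))
    for (run in runs) {
        stopifnot(all(c("precursorMass", "fragMass", "intensity") %in% names(run)))
        for (pm in unique(run$precursorMass)) {
            d <- abs(subunitMasses - pm) / pm * 1e6
            hits <- which(d <= tolerancePpm)
            if (length(hits) == 0L) {
                warning(sprintf(
                    "precursor %.2f Da matches no subunit mass; skipped", pm))
                next
            }
            sel <- run$precursorMass == pm
            # a precursor within tolerance of several subunit masses (near
            # isobaric chains, or one chain reported twice) feeds them all
            for (i in hits) {
                pooledF[[i]] <- c(pooledF[[i]], run$fragMass[sel])
                pooledI[[i]] <- c(pooledI[[i]], run$intensity[sel])
            }
        }
    }
    out <- list()
    for (i in seq_along(subunitMasses)) {
        if (is.null(pooledF[[i]])) next
        o <- order(pooledF[[i]])
        f <- pooledF[[i]][o]; w <- pooledI[[i]][o]
        # merge runs of near-equal masses (within ppm tolerance of the
        # running intensity-weighted mean)
        mf <- numeric(0); mi <- numeric(0)
        cf <- f[1]; ci <- w[1]
        for (j in seq_along(f)[-1]) {
            if (abs(f[j] - cf) / cf * 1e6 <= tolerancePpm) {
                newi <- ci + w[j]
                cf <- (cf * ci + f[j] * w[j]) / newi
                ci <- newi
            } else {
                mf <- c(mf, cf); mi <- c(mi, ci)
                cf <- f[j]; ci <- w[j]
            }
        }
        mf <- c(mf, cf); mi <- c(mi, ci)
        out[[sprintf("%.4f", subunitMasses[i])]] <-
            fragmentMassSet(subunitMasses[i], mf, mi, tolerancePpm, table)
    }
    out
}

#' Error inflation when converting an SRM into a PRM
#'
#' Converting a suffix residue mass into a prefix residue mass by
#' subtracting it from the deconvoluted precursor mass adds the precursor
#' mass error on top of the fragment mass error, which is why assembly uses
#' PRMs left-to-right and SRMs right-to-left instead of converting.
#'
#' @param precursorObs,precursorTrue observed and true precursor masses (Da)
#' @param srmObs observed suffix residue mass (Da)
#' @param suffixTrue true suffix residue mass (Da)
#' @return named numeric: \code{srmError} and \code{convertedPrmError} (Da)
#' @examples
#' srmToPrmError(23001, 23000, 1000.05, 1000)  # 0.05 Da becomes 0.95 Da
#' @export
srmToPrmError <- function(precursorObs, precursorTrue, srmObs, suffixTrue) {
    stopifnot(precursorObs > 0, precursorTrue > 0, srmObs > 0, suffixTrue > 0)
    c(srmError = abs(srmObs - suffixTrue),
      convertedPrmError = abs((precursorObs - srmObs) -
                              (precursorTrue - suffixTrue)))
}

.prefixMasses <- function(x, table) {
    p <- .asTokens(x, table)
    cm <- cumsum(p$mass)
    cm[-length(cm)]
}

# for each observed mass, TRUE when some theoretical mass lies within the
# relative ppm tolerance (sorted-neighbour check, fully vectorized)
.obsMatched <- function(obs, theo, tolPpm) {
    if (length(obs) == 0L || length(theo) == 0L)
        return(logical(length(obs)))
    theo <- sort(theo)
    i <- findInterval(obs, theo)
    # tolerance is relative to the theoretical mass (as in the DP kernel)
    tLo <- theo[pmax(i, 1L)]
    tHi <- theo[pmin(i + 1L, length(theo))]
    (i >= 1L & abs(obs - tLo) <= tolPpm * 1e-6 * tLo) |
        (i < length(theo) & abs(tHi - obs) <= tolPpm * 1e-6 * tHi)
}

# for each theoretical mass, TRUE when some observed mass lies within the
# ppm tolerance of it (tolerance relative to the theoretical mass)
.theoMatched <- function(theo, obs, tolPpm) {
    if (length(theo) == 0L || length(obs) == 0L)
        return(logical(length(theo)))
    obs <- sort(obs)
    i <- findInterval(theo, obs)
    oLo <- obs[pmax(i, 1L)]
    oHi <- obs[pmin(i + 1L, length(obs))]
    tol <- tolPpm * 1e-6 * theo
    (i >= 1L & abs(theo - oLo) <= tol) |
        (i < length(obs) & abs(oHi - theo) <= tol)
}

#' Count middle-down fragment matches for a candidate sequence
#'
#' Number of observed fragment masses (as PRMs for the forward direction,
#' SRMs for the reverse) that fall within ppm tolerance of any theoretical
#' prefix (respectively suffix) residue mass of the candidate.  Each
#' observed fragment counts at most once.
#'
#' @param x candidate sequence (string or \code{\link{parsePeptide}} result)
#' @param fms a \linkS4class{FragmentMassSet}
#' @param direction \code{"forward"} (PRMs against prefix masses) or
#'   \code{"reverse"} (SRMs against suffix masses)
#' @param table a \code{\link{residueTable}}
#' @return integer match count T
#' @export
countMatches <- function(x, fms, direction = c("forward", "reverse"),
                         table = residueTable()) {
    direction <- match.arg(direction)
    p <- .asTokens(x, table)
    if (length(p$mass) < 2L) return(0L)
    theo <- if (direction == "forward") cumsum(p$mass) else cumsum(rev(p$mass))
    theo <- theo[-length(theo)]
    obs <- if (direction == "forward") fms@prm else fms@srm
    if (length(obs) == 0L) return(0L)
    sum(.obsMatched(obs, theo, fms@tolerancePpm))
}

#' Middle-down fragment site coverage
#'
#' Fraction of possible (c, z) fragmentation sites of a sequence supported
#' by an observed fragment within ppm tolerance: matched c sites (prefix
#' masses against the PRM list) plus matched z sites (suffix masses against
#' the SRM list), over 2 (L - 1).
#'
#' @param x candidate sequence (length >= 2)
#' @param fms a \linkS4class{FragmentMassSet}
#' @param table a \code{\link{residueTable}}
#' @return coverage fraction in [0, 1]
#' @export
mdCoverage <- function(x, fms, table = residueTable()) {
    p <- .asTokens(x, table)
    L <- length(p$mass)
    stopifnot(L >= 2L)
    pref <- cumsum(p$mass); pref <- pref[-L]
    suff <- cumsum(rev(p$mass)); suff <- suff[-L]
    cHit <- .theoMatched(pref, fms@prm, fms@tolerancePpm)
    zHit <- .theoMatched(suff, fms@srm, fms@tolerancePpm)
    (sum(cHit) + sum(zHit)) / (2 * (L - 1))
}

#' Matched fragmentation sites of a candidate sequence
#'
#' @param x candidate sequence
#' @param fms a \linkS4class{FragmentMassSet}
#' @param table a \code{\link{residueTable}}
#' @return list with logical vectors \code{cSites} and \code{zSites} (both
#'   indexed by cleavage site 1..L-1, z sites counted from the N terminus)
#' @export
matchedSites <- function(x, fms, table = residueTable()) {
    p <- .asTokens(x, table)
    L <- length(p$mass)
    stopifnot(L >= 2L)
    pref <- cumsum(p$mass)[-L]
    suff <- cumsum(rev(p$mass))[-L]
    cHit <- .theoMatched(pref, fms@prm, fms@tolerancePpm)
    zHit <- rev(.theoMatched(suff, fms@srm, fms@tolerancePpm))
    list(cSites = cHit, zSites = zHit)
}
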
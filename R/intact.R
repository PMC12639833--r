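## Feature-based intact mass deconvolution: RT sliding-window scan merging,
## greedy charge assignment with consecutive-charge support, RT feature
## linking, and targeted inclusion-list generation.

#' Construct a centroid scan
#'
#' @param rt retention time (min)
#' @param mz m/z values (strictly increasing)
#' @param intensity peak intensities (non-negative)
#' @return list of class \code{CentroidScan}
#' @export
centroidScan <- function(rt, mz, intensity) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (any(duplicated(mz))) {
        intensity <- vapply(split(intensity, mz), sum, numeric(1))
        mz <- sort(unique(mz))
    }
    stopifnot(all(intensity >= 0))
    structure(list(rt = rt, mz = mz, intensity = intensity),
              class = "CentroidScan")
}

#' Merge neighbouring scans along retention time
#'
#' A sliding window accumulates neighbouring spectra along RT (default
#' window 0.1 min) by merging peaks of the same m/z: peaks falling in the
#' same RT window and within \code{mzTol} of each other are summed into one
#' peak at the intensity-weighted mean m/z.
#'
#' @param scans list of \code{\link{centroidScan}}, sorted by RT
#' @param window RT window size in min (default 0.1)
#' @param mzTol m/z merge tolerance in Th (default 0.01)
#' @return list of merged \code{CentroidScan}, sorted by RT
#' @export
mergeScans <- function(scans, window = 0.1, mzTol = 0.01) {
    stopifnot(window > 0)
    if (length(scans) == 0L) return(list())
    rts <- vapply(scans, `[[`, numeric(1), "rt")
    stopifnot(!is.unsorted(rts))
    bin <- floor(rts / window)
    out <- list()
    for (b in unique(bin)) {
        grp <- scans[bin == b]
        mz <- unlist(lapply(grp, `[[`, "mz"))
        it <- unlist(lapply(grp, `[[`, "intensity"))
        o <- order(mz)
        mz <- mz[o]; it <- it[o]
        if (length(mz) == 0L) next
        cl <- cumsum(c(TRUE, diff(mz) > mzTol))
        mzM <- vapply(split(seq_along(mz), cl), function(i)
            sum(mz[i] * it[i]) / max(sum(it[i]), .Machine$double.eps),
            numeric(1))
        itM <- vapply(split(it, cl), sum, numeric(1))
        rtM <- mean(vapply(grp, `[[`, numeric(1), "rt"))
        out[[length(out) + 1L]] <- centroidScan(rtM, unname(mzM), unname(itM))
    }
    out[order(vapply(out, `[[`, numeric(1), "rt"))]
}

#' Deconvolute one centroid scan
#'
#' Greedy highest-intensity-first charge assignment: for each unassigned
#' peak, every charge in range is tried; the charge whose implied neutral
#' mass is supported by the most peaks at other charges (theoretical m/z =
#' mass/z + proton within ppm tolerance) wins.  A mass is reported only
#' when supported by at least \code{minPeaks} peaks at distinct charges.
#'
#' @param scan a \code{\link{centroidScan}}
#' @param zRange integer charge range (default 10:40)
#' @param tolPpm m/z match tolerance (default 20)
#' @param minPeaks minimum distinct supporting charges (default 2)
#' @param table a \code{\link{residueTable}}
#' @return data.frame with columns \code{mass}, \code{intensity} and a list
#'   column \code{charges} of per-charge support (z, mz, intensity)
#' @export
deconvoluteScan <- function(scan, zRange = 10:40, tolPpm = 20,
                            minPeaks = 2L, table = residueTable()) {
    stopifnot(length(zRange) > 0)
    proton <- unname(table$constants["proton"])
    mz <- scan$mz; it <- scan$intensity
    n <- length(mz)
    assigned <- logical(n)
    res <- list()
    for (i in order(-it)) {
        if (assigned[i]) next
        bestZ <- NA_integer_; bestSup <- integer(0); bestSupZ <- integer(0)
        for (z in zRange) {
            M <- (mz[i] - proton) * z
            if (M <= 0) next
            sup <- integer(0); supZ <- integer(0)
            for (z2 in zRange) {
                pred <- M / z2 + proton
                cand <- which(!assigned & abs(mz - pred) <= tolPpm * 1e-6 * pred)
                if (length(cand) > 0L) {
                    j <- cand[which.max(it[cand])]
                    sup <- c(sup, j); supZ <- c(supZ, z2)
                }
            }
            if (length(sup) > length(bestSup)) {
                bestZ <- z; bestSup <- sup; bestSupZ <- supZ
            }
        }
        if (length(bestSup) >= minPeaks) {
            M <- sum((mz[bestSup] - proton) * bestSupZ * it[bestSup]) /
                sum(it[bestSup])
            assigned[bestSup] <- TRUE
            res[[length(res) + 1L]] <- list(
                mass = M, intensity = sum(it[bestSup]),
                charges = data.frame(z = bestSupZ, mz = mz[bestSup],
                                     intensity = it[bestSup]))
        } else assigned[i] <- TRUE   # isolated peak: consumed, not reported
    }
    if (length(res) == 0L)
        return(data.frame(mass = numeric(0), intensity = numeric(0)))
    out <- data.frame(mass = vapply(res, `[[`, numeric(1), "mass"),
                      intensity = vapply(res, `[[`, numeric(1), "intensity"))
    out$charges <- lapply(res, `[[`, "charges")
    out
}

.maxRun <- function(x) {
    if (length(x) == 0L) return(0L)
    x <- sort(unique(x))
    max(rle(c(1L, diff(x)))$lengths[rle(c(1L, diff(x)))$values == 1L], 1L)
}

#' Link per-scan deconvolutions into proteoform masses
#'
#' Masses agreeing within tolerance across at least \code{minScans}
#' consecutive merged scans are linked into one proteoform; per-charge
#' features (m/z window, RT window, summed intensity) are built from the
#' supporting peaks, and masses lacking a run of at least
#' \code{minChargeRun} consecutive charges are dropped.
#'
#' @param decon list of per-merged-scan results: each element a list with
#'   \code{rt} and the data.frame from \code{\link{deconvoluteScan}}
#' @param tolPpm mass link tolerance (default 20)
#' @param minScans minimum consecutive merged scans (default 3)
#' @param minChargeRun minimum consecutive-charge run (default 3)
#' @param mode reported mass mode label
#' @return a \linkS4class{ProteoformSet}
#' @export
linkFeatures <- function(decon, tolPpm = 20, minScans = 3L,
                         minChargeRun = 3L,
                         mode = c("monoisotopic", "average")) {
    mode <- match.arg(mode)
    rows <- list()
    for (s in seq_along(decon)) {
        d <- decon[[s]]$result
        if (nrow(d) == 0L) next
        for (k in seq_len(nrow(d)))
            rows[[length(rows) + 1L]] <- list(
                scan = s, rt = decon[[s]]$rt, mass = d$mass[k],
                intensity = d$intensity[k], charges = d$charges[[k]])
    }
    if (length(rows) == 0L)
        return(new("ProteoformSet",
                   table = data.frame(mass = numeric(0), mode = character(0),
                                      abundance = numeric(0),
                                      nFeatures = integer(0)),
                   features = list()))
    ms <- vapply(rows, `[[`, numeric(1), "mass")
    o <- order(ms)
    rows <- rows[o]; ms <- ms[o]
    grp <- cumsum(c(TRUE, diff(ms) / ms[-length(ms)] * 1e6 > tolPpm))
    tabs <- list(); feats <- list()
    for (g in unique(grp)) {
        rr <- rows[grp == g]
        scanIdx <- vapply(rr, `[[`, numeric(1), "scan")
        if (.maxRun(scanIdx) < minScans) next
        ch <- do.call(rbind, lapply(rr, function(r)
            cbind(r$charges, rt = r$rt)))
        zs <- sort(unique(ch$z))
        if (.maxRun(zs) < minChargeRun) next
        fl <- lapply(zs, function(z) {
            sub <- ch[ch$z == z, ]
            apex <- which.max(sub$intensity)
            data.frame(z = z, mzLo = min(sub$mz), mzHi = max(sub$mz),
                       rtLo = min(sub$rt), rtHi = max(sub$rt),
                       intensity = sum(sub$intensity),
                       mzApex = sub$mz[apex], rtApex = sub$rt[apex])
        })
        fdf <- do.call(rbind, fl)
        wInt <- vapply(rr, `[[`, numeric(1), "intensity")
        tabs[[length(tabs) + 1L]] <- data.frame(
            mass = sum(vapply(rr, `[[`, numeric(1), "mass") * wInt) / sum(wInt),
            mode = mode, abundance = sum(wInt),
            nFeatures = nrow(fdf))
        feats[[length(feats) + 1L]] <- fdf
    }
    if (length(tabs) == 0L)
        return(new("ProteoformSet",
                   table = data.frame(mass = numeric(0), mode = character(0),
                                      abundance = numeric(0),
                                      nFeatures = integer(0)),
                   features = list()))
    tb <- do.call(rbind, tabs)
    tb$abundance <- tb$abundance / sum(tb$abundance)
    o <- order(-tb$abundance)
    new("ProteoformSet", table = tb[o, , drop = FALSE], features = feats[o])
}

#' Deconvolute an intact LC-MS run
#'
#' Convenience wrapper: merge scans along RT, deconvolute every merged
#' scan, and link the results into confident proteoform masses with
#' RT-continuous, consecutively charged supporting features.
#'
#' @param scans list of \code{\link{centroidScan}}
#' @param window RT merge window (min)
#' @param mzTol m/z merge tolerance (Th)
#' @param zRange charge range
#' @param tolPpm m/z and mass-link tolerance (ppm)
#' @param minScans,minChargeRun continuity requirements
#' @param mode reported mass mode label
#' @param table a \code{\link{residueTable}}
#' @return a \linkS4class{ProteoformSet}
#' @export
deconvoluteIntact <- function(scans, window = 0.1, mzTol = 0.01,
                              zRange = 10:40, tolPpm = 20, minScans = 3L,
                              minChargeRun = 3L,
                              mode = c("monoisotopic", "average"),
                              table = residueTable()) {
    mode <- match.arg(mode)
    merged <- mergeScans(scans, window, mzTol)
    decon <- lapply(merged, function(s)
        list(rt = s$rt, result = deconvoluteScan(s, zRange, tolPpm,
                                                 table = table)))
    linkFeatures(decon, tolPpm, minScans, minChargeRun, mode)
}

.overlaps <- function(aLo, aHi, bLo, bHi) aLo <= bHi & bLo <= aHi

#' Build the targeted middle-down inclusion list
#'
#' Greedy selection of precursor targets: all features of all proteoforms
#' are sorted by intensity from highest to lowest and picked unless they
#' overlap an already selected feature in both m/z and RT; at most
#' \code{perMass} entries are kept per proteoform mass.  Each entry records
#' the feature's highest-intensity m/z and the corresponding RT window.
#'
#' @param proteoforms a \linkS4class{ProteoformSet}
#' @param perMass entries per proteoform mass (default 4)
#' @return data.frame of class \code{InclusionList} with columns \code{mz},
#'   \code{rtStart}, \code{rtEnd}, \code{z}, \code{parentMass}
#' @export
buildInclusionList <- function(proteoforms, perMass = 4L) {
    stopifnot(perMass >= 1L)
    tb <- proteoformTable(proteoforms)
    fl <- proteoformFeatures(proteoforms)
    if (nrow(tb) == 0L)
        return(structure(data.frame(mz = numeric(0), rtStart = numeric(0),
                                    rtEnd = numeric(0), z = integer(0),
                                    parentMass = numeric(0)),
                         class = c("InclusionList", "data.frame")))
    all <- do.call(rbind, lapply(seq_len(nrow(tb)), function(i) {
        f <- fl[[i]]
        if (is.null(f) || nrow(f) == 0L) return(NULL)
        f$parentMass <- tb$mass[i]
        f$pf <- i
        f
    }))
    sel <- list()
    taken <- integer(nrow(tb))
    for (k in order(-all$intensity)) {
        f <- all[k, ]
        if (taken[f$pf] >= perMass) next
        clash <- FALSE
        for (s in sel) {
            if (.overlaps(f$mzLo, f$mzHi, s$mzLo, s$mzHi) &&
                .overlaps(f$rtLo, f$rtHi, s$rtLo, s$rtHi)) { clash <- TRUE; break }
        }
        if (clash) next
        sel[[length(sel) + 1L]] <- f
        taken[f$pf] <- taken[f$pf] + 1L
    }
    out <- do.call(rbind, lapply(sel, function(f)
        data.frame(mz = f$mzApex, rtStart = f$rtLo, rtEnd = f$rtHi,
                   z = f$z, parentMass = f$parentMass)))
    if (is.null(out))
        out <- data.frame(mz = numeric(0), rtStart = numeric(0),
                          rtEnd = numeric(0), z = integer(0),
                          parentMass = numeric(0))
    structure(out, class = c("InclusionList", "data.frame"))
}
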
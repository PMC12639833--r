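## Discretized-mass dynamic-programming assembly of one subunit: a forward
## pass seeded with start peptides and scored against PRMs, a reverse pass
## seeded with end peptides and scored against SRMs, and a merge of the two
## directions at a shared peptide.

#' Discretize a mass
#'
#' Nearest-integer index of \code{mass / width}; with the default width of
#' 0.1 Da a mass of 111.2 Da has index 1112.
#'
#' @param mass mass in Da (non-negative)
#' @param width discretization width in Da (default 0.1)
#' @return integer index
#' @examples
#' discretizeMass(111.2)   # 1112
#' @export
discretizeMass <- function(mass, width = 0.1) {
    if (any(mass < 0)) stop("mass must be non-negative")
    stopifnot(width > 0)
    as.integer(round(mass / width))
}

# Reconstruct the realized residue string of a DP path: the first peptide
# contributes fully, each subsequent peptide its residues beyond the
# overlap.  Returns per-residue tokens, masses, accumulated and local
# confidence, source peptide/position, and the realized end position of
# every path peptide.
.realizePath <- function(peptides, acc, pepIds, bFrom) {
    tokens <- character(0); mass <- numeric(0)
    aconf <- numeric(0); lconf <- numeric(0)
    src <- integer(0); srcPos <- integer(0)
    pepEnds <- integer(length(pepIds))
    for (s in seq_along(pepIds)) {
        p <- pepIds[s]
        from <- if (s == 1L) 1L else bFrom[s]
        idx <- seq.int(from, length(peptides@residues[[p]]))
        tokens <- c(tokens, peptides@residues[[p]][idx])
        mass <- c(mass, peptides@residueMass[[p]][idx])
        aconf <- c(aconf, acc[[p]][idx])
        lconf <- c(lconf, peptides@confidence[[p]][idx])
        src <- c(src, rep(p, length(idx)))
        srcPos <- c(srcPos, idx)
        pepEnds[s] <- length(tokens)
    }
    list(tokens = tokens, mass = mass, acc = aconf, local = lconf,
         src = src, srcPos = srcPos, pepEnds = pepEnds)
}

# Run the DP kernel for one or more target masses; returns, per target, the
# realized candidate list.
.dpPass <- function(graph, startIds, frags, tolPpm, targets, width,
                    capacity, endIds, penalty, massTol, lowConf, topK,
                    table, beamMargin = Inf) {
    if (length(startIds) == 0L)
        stop(errorCondition("no start peptides for this subunit type",
                            class = c("abseqms_no_start", "error")))
    # intact subunit masses include one water; DP path masses are residue
    # sums, so targets are water-corrected here
    targets <- targets - unname(table$constants["waterMono"])
    ed <- graph@edges
    raw <- cpp_dp_assemble(
        graph@peptides@residueMass, graph@accConfidence,
        as.integer(ed$from), as.integer(ed$to),
        as.integer(ed$bConsumed + 1L),
        as.integer(startIds), as.integer(endIds),
        as.numeric(frags), tolPpm, as.numeric(targets), width,
        as.integer(capacity), massTol, lowConf, penalty,
        unname(table$constants["averagineResidueMass"]), as.integer(topK),
        as.numeric(beamMargin))
    lapply(raw, function(perTarget) lapply(perTarget, function(cand) {
        r <- .realizePath(graph@peptides, graph@accConfidence,
                          cand$peptides, cand$bFrom)
        c(cand[c("peptides", "bFrom", "T", "NU", "score", "finalScore",
                 "endOk")],
          r,   # per-residue bookkeeping; r$mass is the residue-mass vector
          list(totalMass = cand$mass,
               sequence = paste(r$tokens, collapse = "")))
    }))
}

# natural-orientation view of a candidate realized on the reversed graph
.unreverseCandidate <- function(cand, pepLengths) {
    L <- length(cand$tokens)
    cand$pepStarts <- L - cand$pepEnds + 1L
    cand$pepLens <- pepLengths[cand$peptides]
    cand$tokens <- rev(cand$tokens)
    cand$mass <- rev(cand$mass)
    cand$acc <- rev(cand$acc)
    cand$local <- rev(cand$local)
    cand$src <- rev(cand$src)
    cand$srcPos <- pepLengths[cand$src] - rev(cand$srcPos) + 1L
    cand$sequence <- paste(cand$tokens, collapse = "")
    cand$direction <- "reverse"
    cand
}

#' Forward assembly pass
#'
#' Populates the DP table with the start peptides of the attempted subunit
#' type and extends paths peptide-by-peptide along forward overlap edges.
#' Each path lives at the discretized index of its total residue mass and is
#' scored \code{s(p) = T + (NA - NU)}: T middle-down PRM matches, NA the
#' mass divided by the averagine residue mass, NU the number of residues
#' with accumulated confidence below \code{lowConf}.  Buckets keep the
#' \code{capacity} best paths.  Terminal candidates are paths within
#' \code{massTol} Da of the subunit mass; candidates not ending in an end
#' peptide carry a score penalty.
#'
#' @param graph an \linkS4class{OverlapGraph} with accumulated confidence
#' @param startIds indices of start peptides for the attempted type
#' @param fms a \linkS4class{FragmentMassSet} (or NULL for no middle-down
#'   guidance, in which case scores reduce to NA - NU)
#' @param subunitMass target neutral monoisotopic subunit mass (Da)
#' @param width discretization width (Da, default 0.1)
#' @param capacity bounded priority-queue capacity per mass index (10)
#' @param endIds indices of end peptides (for the terminal penalty)
#' @param penalty score penalty for paths ending outside the end set (5)
#' @param massTol terminal mass tolerance (4 Da)
#' @param lowConf unconfident-residue threshold (0.5)
#' @param topK candidates returned (10)
#' @param table a \code{\link{residueTable}}
#' @return list of candidates ordered by penalized score; each has the
#'   realized \code{sequence}, per-residue bookkeeping, \code{mass},
#'   \code{T}, \code{NU}, \code{score}, \code{finalScore} and \code{endOk}
#' @export
forwardPass <- function(graph, startIds, fms, subunitMass, width = 0.1,
                        capacity = 10L, endIds = integer(0), penalty = 5,
                        massTol = 4, lowConf = 0.5, topK = 10L,
                        table = residueTable()) {
    frags <- if (is.null(fms)) numeric(0) else fms@prm
    tolPpm <- if (is.null(fms)) 50 else fms@tolerancePpm
    out <- .dpPass(graph, startIds, frags, tolPpm, subunitMass, width,
                   capacity, endIds, penalty, massTol, lowConf, topK,
                   table)[[1]]
    for (i in seq_along(out)) out[[i]]$direction <- "forward"
    out
}

# Reverse every peptide of a set (residue order, confidence, w-ion)
.reversePeptides <- function(peptides) {
    new("DeNovoPeptideSet",
        sequence = vapply(peptides@residues,
                          function(r) paste(rev(r), collapse = ""), character(1)),
        residues = lapply(peptides@residues, rev),
        residueMass = lapply(peptides@residueMass, rev),
        confidence = lapply(peptides@confidence, rev),
        alc = peptides@alc, mode = peptides@mode,
        spectrumId = peptides@spectrumId,
        wIon = lapply(peptides@wIon, rev))
}

#' Reversed overlap graph
#'
#' Builds the overlap graph of the residue-reversed peptides, used by the
#' reverse assembly pass.  Constructing it once and passing it to
#' \code{\link{sequenceSubunit}} avoids rebuilding per subunit.
#'
#' @param graph an \linkS4class{OverlapGraph}
#' @return an \linkS4class{OverlapGraph} over reversed peptides
#' @export
reverseGraph <- function(graph) {
    buildOverlapGraph(.reversePeptides(graph@peptides),
                      minBlocks = graph@minBlocks, accumulate = TRUE)
}

#' Reverse assembly pass
#'
#' Mirror of \code{\link{forwardPass}}: the DP is seeded with the subunit's
#' end peptides and extends right-to-left, scoring against SRMs (every
#' fragment read as a z ion).  Internally the peptides are residue-reversed
#' so the same DP kernel applies; returned candidates are reported in
#' natural (N-to-C) orientation.
#'
#' @inheritParams forwardPass
#' @param endSeedIds indices of end peptides used as seeds
#' @param startIds indices of start peptides (terminal set of this pass)
#' @param revGraph optional precomputed \code{\link{reverseGraph}}
#' @export
reversePass <- function(graph, endSeedIds, fms, subunitMass, width = 0.1,
                        capacity = 10L, startIds = integer(0), penalty = 5,
                        massTol = 4, lowConf = 0.5, topK = 10L,
                        table = residueTable(), revGraph = NULL) {
    if (is.null(revGraph)) revGraph <- reverseGraph(graph)
    frags <- if (is.null(fms)) numeric(0) else fms@srm
    tolPpm <- if (is.null(fms)) 50 else fms@tolerancePpm
    out <- .dpPass(revGraph, endSeedIds, frags, tolPpm, subunitMass, width,
                   capacity, startIds, penalty, massTol, lowConf, topK,
                   table)[[1]]
    lapply(out, .unreverseCandidate,
           pepLengths = lengths(graph@peptides@residues))
}

#' Re-apply the terminal-peptide penalty
#'
#' @param candidates candidate list from a DP pass
#' @param endIds indices forming the end set of the attempted type
#' @param penalty score reduction for candidates whose final peptide is not
#'   in the end set
#' @return candidates with updated \code{finalScore} and \code{endOk},
#'   re-ordered by penalized score
#' @export
applyEndPenalty <- function(candidates, endIds, penalty = 5) {
    for (i in seq_along(candidates)) {
        last <- candidates[[i]]$peptides[length(candidates[[i]]$peptides)]
        ok <- last %in% endIds
        candidates[[i]]$endOk <- ok
        candidates[[i]]$finalScore <-
            candidates[[i]]$score - if (ok) 0 else penalty
    }
    candidates[order(-vapply(candidates, `[[`, numeric(1), "finalScore"))]
}

.countFragMatches <- function(theo, obs, tolPpm)
    sum(.obsMatched(obs, theo, tolPpm))

#' Merge forward and reverse assembly candidates
#'
#' Pairs forward and reverse candidates that share a peptide, splices the
#' forward realization up to the shared peptide's end with the reverse
#' realization beyond it, and keeps merged sequences whose total mass is
#' within tolerance of the subunit mass.  Ranking is by total middle-down
#' matches: PRM matches on the left of the junction plus SRM matches on the
#' right (the junction boundary counted once).
#'
#' @param fwd,rev candidate lists from \code{\link{forwardPass}} and
#'   \code{\link{reversePass}}
#' @param fms the subunit's \linkS4class{FragmentMassSet} (or NULL)
#' @param subunitMass target subunit mass (Da)
#' @param pepSumMass numeric vector of total residue masses per graph
#'   peptide (\code{vapply(residueMass, sum, 1)}), used to locate the exact
#'   junction boundary inside the shared read
#' @param massTol mass tolerance (4 Da)
#' @param topK merged candidates returned (10)
#' @param table a \code{\link{residueTable}}
#' @return list of merged candidates (possibly empty when no pair shares a
#'   peptide within mass tolerance), each carrying \code{junction} (realized
#'   position of the splice)
#' @export
mergeDirections <- function(fwd, rev, fms, subunitMass, pepSumMass,
                            massTol = 4, topK = 10L,
                            table = residueTable()) {
    residueTarget <- subunitMass - unname(table$constants["waterMono"])
    # exact-boundary lookup in a cumulative-mass vector
    findBoundary <- function(cm, m, tol = 1e-6) {
        i <- findInterval(m - tol, cm) + 1L
        if (i >= 1L && i <= length(cm) && abs(cm[i] - m) <= tol) i else NA_integer_
    }
    merged <- list()
    seen <- character(0)
    for (f in fwd) {
        cumF <- cumsum(f$mass)
        for (r in rev) {
            shared <- intersect(f$peptides, r$peptides)
            if (length(shared) == 0L) next
            cumR <- cumsum(r$mass)
            for (p in shared) {
                # the shared read's realized span carries exactly the read's
                # mass in both paths (mass-block alignment conserves segment
                # mass), so its far boundary is located by adding the read
                # mass to the near, exactly book-kept boundary; positional
                # bookkeeping would drift under isobaric length changes and
                # prefix masses differ between the two halves, local mass
                # anchors do not
                pMass <- pepSumMass[p]
                e <- f$pepEnds[match(p, f$peptides)]
                jR <- r$pepStarts[match(p, r$peptides)]
                cuts <- list()
                if (!is.na(e) && e >= 1L && e <= length(f$tokens)) {
                    # cut at p's end: r-side boundary = (mass before p) + p
                    B0r <- if (!is.na(jR) && jR > 1L) cumR[jR - 1L] else 0
                    k <- findBoundary(cumR, B0r + pMass)
                    if (!is.na(k))
                        cuts[[length(cuts) + 1L]] <- c(fEnd = e, rFrom = k + 1L)
                }
                if (!is.na(jR) && jR >= 1L && jR <= length(r$tokens) &&
                    !is.na(e)) {
                    # cut at p's start: f-side boundary = (mass to p's end) - p
                    k2 <- findBoundary(cumF, cumF[e] - pMass)
                    if (!is.na(k2))
                        cuts[[length(cuts) + 1L]] <- c(fEnd = k2, rFrom = jR)
                }
                for (ct in cuts) {
                    e2 <- ct[["fEnd"]]; rf <- ct[["rFrom"]]
                    if (e2 < 1L || rf > length(r$tokens) + 1L) next
                    idxF <- seq_len(e2)
                    idxR <- if (rf > length(r$tokens)) integer(0) else
                        seq.int(rf, length(r$tokens))
                    total <- cumF[e2] +
                        (if (length(idxR)) cumR[length(cumR)] -
                             (if (rf > 1L) cumR[rf - 1L] else 0) else 0)
                    if (abs(total - residueTarget) > massTol) next
                    tokens <- c(f$tokens[idxF], r$tokens[idxR])
                    seqStr <- paste(tokens, collapse = "")
                    if (seqStr %in% seen) next
                    seen <- c(seen, seqStr)
                    mass <- c(f$mass[idxF], r$mass[idxR])
                    cm <- cumsum(mass)
                    L <- length(mass)
                    Tleft <- Tright <- 0L
                    if (!is.null(fms) && L >= 2L) {
                        tol <- fms@tolerancePpm
                        pref <- cm[-L]
                        leftB <- pref[seq_len(min(e2, L - 1L))]
                        Tleft <- .countFragMatches(leftB, fms@prm, tol)
                        suff <- cm[L] - cm
                        rightB <- suff[min(e2, L - 1L):(L - 1L)]
                        rightB <- rightB[rightB > 0]
                        Tright <- .countFragMatches(rightB, fms@srm, tol)
                    }
                    merged[[length(merged) + 1L]] <- list(
                        tokens = tokens, sequence = seqStr, mass = mass,
                        totalMass = total,
                        T = Tleft + Tright, junction = e2,
                        acc = c(f$acc[idxF], r$acc[idxR]),
                        local = c(f$local[idxF], r$local[idxR]),
                        src = c(f$src[idxF], r$src[idxR]),
                        srcPos = c(f$srcPos[idxF], r$srcPos[idxR]),
                        peptides = c(f$peptides, r$peptides),
                        direction = "merged")
                }
            }
        }
    }
    if (length(merged) == 0L) return(list())
    ord <- order(-vapply(merged, `[[`, numeric(1), "T"))
    merged[ord[seq_len(min(topK, length(merged)))]]
}

.candidateTotalT <- function(cand, fms, table) {
    if (is.null(fms)) return(0L)
    countMatches(list(tokens = cand$tokens, mass = cand$mass,
                      letters = substr(cand$tokens, 1, 1)),
                 fms, "forward", table) +
    countMatches(list(tokens = cand$tokens, mass = cand$mass,
                      letters = substr(cand$tokens, 1, 1)),
                 fms, "reverse", table)
}

#' Sequence all subunits in amortized DP sweeps
#'
#' Runs one forward and one reverse DP per subunit type (six sweeps total)
#' with all subunit masses as simultaneous targets and the pooled PRM
#' (respectively SRM) lists of all subunits as expansion guidance -- a
#' chain's prefix masses match essentially only its own subunit's
#' fragments, so pooled guidance ranks partial paths the same way while
#' amortizing the traversal.  Candidates are then merged and ranked per
#' subunit against that subunit's own \linkS4class{FragmentMassSet}
#' (exact per-subunit match counts), mirroring
#' \code{\link{sequenceSubunit}}'s per-type selection.
#'
#' @inheritParams sequenceSubunit
#' @param beamMargin score margin of the heuristic expansion beam
#'   (\code{Inf} disables pruning and restores the exact bounded-queue DP)
#' @param fmsList named list of per-subunit \linkS4class{FragmentMassSet}
#'   (names \code{sprintf("\%.4f", subunitMasses)}; missing entries allowed)
#' @param subunitMasses deconvoluted subunit masses (Da)
#' @return named list (one per subunit mass) of \code{\link{sequenceSubunit}}
#'   result structures
#' @export
assembleSubunits <- function(graph, termSets, fmsList, subunitMasses,
                             width = 0.1, capacity = 10L, penalty = 5,
                             massTol = 4, lowConf = 0.5, topK = 10L,
                             revGraph = NULL, table = residueTable(),
                             beamMargin = 30) {
    if (is.null(revGraph)) revGraph <- reverseGraph(graph)
    keys <- sprintf("%.4f", subunitMasses)
    have <- !vapply(fmsList[keys], is.null, logical(1))
    # near-duplicate masses are collapsed when pooling: near-isobaric
    # subunits share precursors and would otherwise contribute their
    # fragments twice, skewing the pooled expansion guidance between
    # chains of one type
    dedupe <- function(x) {
        x <- sort(x)
        if (length(x) < 2L) return(x)
        x[c(TRUE, diff(x) / x[-1] > 1e-5)]
    }
    pooledPrm <- dedupe(unlist(lapply(fmsList[keys[have]], prmList)))
    pooledSrm <- dedupe(unlist(lapply(fmsList[keys[have]], srmList)))
    tolPpm <- if (any(have)) fmsList[keys[have]][[1]]@tolerancePpm else 50
    pepLens <- lengths(graph@peptides@residues)
    pepSumMass <- vapply(graph@peptides@residueMass, sum, numeric(1))

    # candidates are collected deeper than the reported top-k: the pooled
    # DP score only surfaces them, the exact per-subunit match count ranks
    # them (this matters when two subunit masses sit within one candidate
    # window of each other)
    collectK <- max(topK, 50L)
    fwdAll <- revAll <- list()
    for (type in names(termSets)) {
        ts <- termSets[[type]]
        if (length(ts$start) == 0L || length(ts$end) == 0L) next
        fwdAll[[type]] <- .dpPass(graph, ts$start, pooledPrm, tolPpm,
                                  subunitMasses, width, capacity, ts$end,
                                  penalty, massTol, lowConf, collectK, table,
                                  beamMargin)
        revAll[[type]] <- .dpPass(revGraph, ts$end, pooledSrm, tolPpm,
                                  subunitMasses, width, capacity, ts$start,
                                  penalty, massTol, lowConf, collectK, table,
                                  beamMargin)
    }
    out <- list()
    for (i in seq_along(subunitMasses)) {
        fms <- fmsList[[keys[i]]]
        attempts <- list()
        for (type in names(termSets)) {
            ts <- termSets[[type]]
            if (length(ts$start) == 0L || length(ts$end) == 0L) {
                attempts[[type]] <- list(status = "no start/end peptides",
                                         candidates = list())
                next
            }
            fwd <- fwdAll[[type]][[i]]
            for (k in seq_along(fwd)) fwd[[k]]$direction <- "forward"
            rev <- lapply(revAll[[type]][[i]], .unreverseCandidate,
                          pepLengths = pepLens)
            cands <- c(mergeDirections(fwd[seq_len(min(topK, length(fwd)))],
                                       rev[seq_len(min(topK, length(rev)))],
                                       fms, subunitMasses[i],
                                       pepSumMass, massTol, topK), fwd, rev)
            cands <- cands[!duplicated(vapply(cands, `[[`, character(1),
                                              "sequence"))]
            if (length(cands) == 0L) {
                attempts[[type]] <- list(status = "no candidates",
                                         candidates = list())
                next
            }
            tt <- vapply(cands, .candidateTotalT, numeric(1), fms = fms,
                         table = table)
            ord <- order(-tt)
            keep <- ord[seq_len(min(topK, length(ord)))]
            best <- cands[[ord[1]]]
            best$totalT <- tt[ord[1]]
            attempts[[type]] <- list(status = "ok",
                                     candidates = cands[keep],
                                     best = best)
        }
        ok <- names(attempts)[vapply(attempts, function(a)
            identical(a$status, "ok"), logical(1))]
        out[[keys[i]]] <- if (length(ok) == 0L)
            list(winner = NULL, type = NA_character_, attempts = attempts,
                 status = "unsequenceable")
        else {
            tBest <- vapply(ok, function(t) attempts[[t]]$best$totalT,
                            numeric(1))
            type <- ok[which.max(tBest)]
            list(winner = attempts[[type]]$best, type = type,
                 attempts = attempts,
                 status = if (is.null(fms)) "no-middledown" else "ok")
        }
    }
    out
}

#' Sequence one subunit, attempting all three subunit types
#'
#' Runs the forward pass, reverse pass and directional merge once per
#' subunit type (LC, Fd, Fc/2), each with that type's start and end peptide
#' sets, and reports the type whose best candidate carries the most
#' middle-down fragment matches (c plus z, counted on the full candidate).
#' A type with an empty start or end set aborts cleanly; when every type
#' fails the subunit is reported unsequenceable.
#'
#' @param graph an \linkS4class{OverlapGraph} with accumulated confidence
#' @param termSets start/end sets from \code{\link{terminusSets}}
#' @param fms the subunit's \linkS4class{FragmentMassSet} (or NULL; scores
#'   then reduce to the confidence terms and the result is flagged)
#' @param subunitMass deconvoluted neutral monoisotopic subunit mass
#' @param width,capacity,penalty,massTol,lowConf,topK DP settings, see
#'   \code{\link{forwardPass}}
#' @param revGraph optional precomputed \code{\link{reverseGraph}}
#' @param table a \code{\link{residueTable}}
#' @return list with \code{winner} (best candidate or NULL), \code{type}
#'   (winning subunit type), \code{attempts} (per-type diagnostics) and
#'   \code{status} (\code{"ok"}, \code{"no-middledown"} or
#'   \code{"unsequenceable"})
#' @export
sequenceSubunit <- function(graph, termSets, fms, subunitMass, width = 0.1,
                            capacity = 10L, penalty = 5, massTol = 4,
                            lowConf = 0.5, topK = 10L, revGraph = NULL,
                            table = residueTable()) {
    if (is.null(revGraph)) revGraph <- reverseGraph(graph)
    attempts <- list()
    for (type in names(termSets)) {
        ts <- termSets[[type]]
        if (length(ts$start) == 0L || length(ts$end) == 0L) {
            attempts[[type]] <- list(status = "no start/end peptides",
                                     candidates = list())
            next
        }
        fwd <- tryCatch(
            forwardPass(graph, ts$start, fms, subunitMass, width, capacity,
                        ts$end, penalty, massTol, lowConf, topK, table),
            abseqms_no_start = function(e) list())
        rev <- tryCatch(
            reversePass(graph, ts$end, fms, subunitMass, width, capacity,
                        ts$start, penalty, massTol, lowConf, topK, table,
                        revGraph = revGraph),
            abseqms_no_start = function(e) list())
        cands <- c(mergeDirections(fwd, rev, fms, subunitMass,
                                   vapply(graph@peptides@residueMass, sum,
                                          numeric(1)),
                                   massTol, topK),
                   fwd, rev)
        if (length(cands) == 0L) {
            attempts[[type]] <- list(status = "no candidates",
                                     candidates = list())
            next
        }
        tt <- vapply(cands, .candidateTotalT, numeric(1), fms = fms,
                     table = table)
        best <- cands[[which.max(tt)]]
        best$totalT <- max(tt)
        attempts[[type]] <- list(status = "ok", candidates = cands,
                                 best = best)
    }
    ok <- names(attempts)[vapply(attempts, function(a)
        identical(a$status, "ok"), logical(1))]
    if (length(ok) == 0L)
        return(list(winner = NULL, type = NA_character_, attempts = attempts,
                    status = "unsequenceable"))
    tBest <- vapply(ok, function(t) attempts[[t]]$best$totalT, numeric(1))
    type <- ok[which.max(tBest)]
    list(winner = attempts[[type]]$best, type = type, attempts = attempts,
         status = if (is.null(fms)) "no-middledown" else "ok")
}
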
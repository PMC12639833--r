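## End-to-end orchestration: filtered reads -> overlap graph -> per-subunit
## assembly -> refinement -> antibody pairing, with optional truth-based
## metrics.

#' Pipeline configuration
#'
#' All tunable tolerances and defaults in one place; the resolved
#' configuration is attached to every pipeline result.
#'
#' @param width DP mass discretization width (Da)
#' @param mergeWindow intact RT merge window (min)
#' @param mdTolPpm middle-down fragment match tolerance (ppm)
#' @param subunitTolDa terminal/merge/pairing mass tolerance (Da)
#' @param wholeTolPpm whole-antibody mass tolerance (ppm)
#' @param minAlc ALC filter threshold
#' @param maxLowConfRun longest tolerated unconfident run
#' @param lowConf unconfident-residue threshold
#' @param capacity DP priority-queue capacity
#' @param inclusionPerMass inclusion-list entries per proteoform mass
#' @param topK assembly candidates reported per subunit
#' @param refineTopK refined candidate sequences kept
#' @param penalty end-peptide score penalty
#' @param minBlocks minimum mass blocks per overlap edge
#' @param disulfides disulfide bonds per whole antibody
#' @param enzyme hinge protease (\code{"IdeS"} or \code{"SpeB"})
#' @return list of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(width = 0.1, mergeWindow = 0.1, mdTolPpm = 50,
                           subunitTolDa = 4, wholeTolPpm = 100,
                           minAlc = 0.7, maxLowConfRun = 4L, lowConf = 0.5,
                           capacity = 10L, inclusionPerMass = 4L,
                           topK = 10L, refineTopK = 5L, penalty = 5,
                           minBlocks = 3L, disulfides = 16L,
                           enzyme = "IdeS") {
    structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full sequencing pipeline
#'
#' Executes the workflow on an input bundle: peptide filtering and
#' Leu-space conversion, overlap-graph construction with confidence
#' accumulation, terminus classification, per-subunit aggregation of
#' middle-down fragments, three-type DP assembly with directional merge,
#' isobaric refinement with Ile/Leu resolution, and intact-mass antibody
#' pairing.  When middle-down input is missing for a subunit, assembly
#' proceeds with T = 0 and a warning.
#'
#' @param bundle list with \code{peptides} (a
#'   \linkS4class{DeNovoPeptideSet}), \code{mdRuns} (per-run fragment
#'   data.frames), and \linkS4class{ProteoformSet}s \code{subunit},
#'   \code{reduced}, \code{whole} (as produced by
#'   \code{\link{simulateDataset}} or read from files)
#' @param config a \code{\link{pipelineConfig}}
#' @param truth optional ground truth (as in \code{\link{simulateDataset}})
#'   enabling residue-accuracy metrics
#' @param table a \code{\link{residueTable}}
#' @param verbose print progress
#' @return list with \code{subunits} (per-subunit assembly results),
#'   \code{sequences} (refined token vectors named by subunit mass),
#'   \code{hcPairs}, \code{groups} (antibody-group table),
#'   \code{metrics} (when truth is given) and \code{config}
#' @export
runPipeline <- function(bundle, config = pipelineConfig(), truth = NULL,
                        table = residueTable(), verbose = FALSE) {
    say <- function(...) if (verbose) message(...)
    pep <- filterPeptides(bundle$peptides, config$minAlc,
                          config$maxLowConfRun, config$lowConf)
    pep <- convertIleToLeu(pep)
    say(length(pep), " peptides after filtering")
    graph <- buildOverlapGraph(pep, config$minBlocks, accumulate = TRUE)
    say(nrow(graphEdges(graph)), " overlap edges")
    classes <- classifyTerminus(pep)
    tsets <- terminusSets(classes)
    revG <- reverseGraph(graph)

    subMass <- proteoformTable(bundle$subunit)$mass
    fmsList <- aggregatePrecursors(bundle$mdRuns, subMass, config$mdTolPpm,
                                   table)
    missing <- setdiff(sprintf("%.4f", subMass), names(fmsList))
    if (length(missing) > 0)
        warning(sprintf(
            "no middle-down fragments for subunit(s) %s; assembling with T = 0",
            paste(missing, collapse = ", ")))
    assembled <- assembleSubunits(graph, tsets, fmsList, subMass,
                                  width = config$width,
                                  capacity = config$capacity,
                                  penalty = config$penalty,
                                  massTol = config$subunitTolDa,
                                  lowConf = config$lowConf,
                                  topK = config$topK, revGraph = revG,
                                  table = table)
    # near-isobaric subunits can attract the same winning sequence (their
    # fragment lists are observationally mixed); each proteoform mass is a
    # distinct species, so the mass that fits the winner best keeps it and
    # the others fall back to their best mass-distinct candidate
    waterMono <- unname(table$constants["waterMono"])
    winSeq <- vapply(assembled, function(s)
        if (is.null(s$winner)) NA_character_ else s$winner$sequence,
        character(1))
    for (sq in unique(winSeq[duplicated(winSeq) & !is.na(winSeq)])) {
        ks <- names(assembled)[!is.na(winSeq) & winSeq == sq]
        # per key: the shared winner plus its best mass-distinct alternative
        pool <- list()
        for (k in ks) {
            fms <- fmsList[[k]]
            w <- assembled[[k]]$winner
            pool[[k]] <- list(list(cand = w, type = assembled[[k]]$type,
                                   shared = TRUE,
                                   fit = abs(w$totalMass + waterMono -
                                             as.numeric(k))))
            # the best alternative is the strongest candidate of a
            # *different species*: isobaric rewrites of the shared chain
            # are nearly identical to it, a genuine twin chain differs
            # across its whole variable region, so candidates more than
            # 90 percent identical to the shared sequence are excluded
            alt <- NULL; altT <- -Inf; altType <- NA_character_
            altFit <- Inf
            for (type in names(assembled[[k]]$attempts)) {
                at <- assembled[[k]]$attempts[[type]]
                if (!identical(at$status, "ok")) next
                for (cand in at$candidates) {
                    if (identical(cand$sequence, sq)) next
                    sim <- tryCatch(residueAccuracy(cand$sequence, sq),
                                    error = function(e) 1)
                    if (sim >= 0.9) next
                    tt <- .candidateTotalT(cand, fms, table)
                    fit <- abs(cand$totalMass + waterMono - as.numeric(k))
                    if (tt > altT || (tt == altT && fit < altFit)) {
                        alt <- cand; altT <- tt; altType <- type
                        altFit <- fit
                    }
                }
            }
            if (!is.null(alt)) {
                alt$totalT <- altT
                pool[[k]][[2]] <- list(cand = alt, type = altType,
                                       shared = FALSE,
                                       fit = abs(alt$totalMass + waterMono -
                                                 as.numeric(k)))
            }
        }
        # greedy joint assignment by mass fit: the shared sequence goes to
        # at most one key, alternatives only to their own key
        open <- ks; sharedUsed <- FALSE
        repeat {
            best <- NULL; bestFit <- Inf
            for (k in open) for (e in pool[[k]]) {
                if (e$shared && sharedUsed) next
                if (e$fit < bestFit) { best <- list(k = k, e = e); bestFit <- e$fit }
            }
            if (is.null(best)) break
            k <- best$k; e <- best$e
            if (!identical(assembled[[k]]$winner$sequence, e$cand$sequence)) {
                assembled[[k]]$winner <- e$cand
                assembled[[k]]$type <- e$type
                say(sprintf(
                    "subunit %s: duplicate winner reassigned to %s candidate",
                    k, e$type))
            }
            if (e$shared) sharedUsed <- TRUE
            open <- setdiff(open, k)
        }
    }

    subunits <- list()
    sequences <- list()
    for (i in seq_along(subMass)) {
        key <- sprintf("%.4f", subMass[i])
        fms <- fmsList[[key]]
        res <- assembled[[key]]
        if (!is.null(res$winner)) {
            res$winner <- refineCandidate(res$winner, pep,
                                          lowConf = config$lowConf,
                                          minSupport = 2L,
                                          topK = config$refineTopK,
                                          table = table)
            res$winner$mdCoverage <- if (!is.null(fms))
                mdCoverage(list(tokens = res$winner$tokens,
                                mass = res$winner$mass,
                                letters = substr(res$winner$tokens, 1, 1)),
                           fms, table) else NA_real_
            sequences[[key]] <- res$winner$tokens
        }
        say(sprintf("subunit %.2f Da -> %s (%s)", subMass[i],
                    res$type, res$status))
        subunits[[key]] <- res
    }

    types <- vapply(subunits, function(s)
        if (is.null(s$winner)) NA_character_ else s$type, character(1))
    lcList <- sequences[which(types == "LC")]
    fdList <- sequences[which(types == "Fd")]
    fc2List <- sequences[which(types == "Fc2")]

    hcPairs <- pairHeavyChains(fdList, fc2List, bundle$reduced, pep,
                               enzyme = config$enzyme,
                               tolDa = config$subunitTolDa, table = table)
    groups <- pairAntibodies(lcList, hcPairs, bundle$whole, bundle$reduced,
                             disulfides = config$disulfides,
                             tolPpm = config$wholeTolPpm,
                             tolDaLc = config$subunitTolDa, table = table)
    out <- list(subunits = subunits, sequences = sequences,
                types = types, hcPairs = hcPairs, groups = groups,
                config = config)
    if (!is.null(truth)) out$metrics <- pipelineMetrics(out, truth)
    out
}

#' Score a pipeline result against simulation truth
#'
#' @param result output of \code{\link{runPipeline}}
#' @param truth the \code{truth} element of \code{\link{simulateDataset}}
#' @return list with \code{perSubunit} (data.frame: subunit chain, matched
#'   assembly, accuracy, length), \code{identity} (length-weighted mean
#'   residue accuracy), \code{pairingsRecovered} and \code{pairingsTrue}
#' @export
pipelineMetrics <- function(result, truth) {
    ch <- truth$chainSet
    subs <- ch$subunits
    keys <- names(result$sequences)
    # injective greedy matching of truth chains to assembled sequences:
    # by accuracy among mass-compatible (within 10 Da) pairs, so that
    # near-isobaric twins (whose key assignment is unknowable from mass)
    # are still credited to the chain they actually sequence
    keyOfChain <- setNames(rep(NA_character_, nrow(subs)), subs$chain)
    if (length(keys) > 0L) {
        am <- matrix(-Inf, nrow(subs), length(keys),
                     dimnames = list(subs$chain, keys))
        for (i in seq_len(nrow(subs))) for (j in seq_along(keys)) {
            if (abs(subs$massMono[i] - as.numeric(keys[j])) > 10) next
            am[i, j] <- residueAccuracy(result$sequences[[keys[j]]],
                                        ch$chains[[subs$chain[i]]])
        }
        while (any(is.finite(am)) && max(am) > -Inf) {
            i <- which(am == max(am), arr.ind = TRUE)[1, ]
            keyOfChain[rownames(am)[i[1]]] <- colnames(am)[i[2]]
            am[i[1], ] <- -Inf
            am[, i[2]] <- -Inf
        }
    }
    rows <- list()
    for (k in seq_len(nrow(subs))) {
        key <- keyOfChain[[subs$chain[k]]]
        acc <- if (is.na(key)) 0 else
            residueAccuracy(result$sequences[[key]],
                            ch$chains[[subs$chain[k]]])
        rows[[k]] <- data.frame(chain = subs$chain[k], type = subs$type[k],
                                length = subs$length[k],
                                assembled = if (is.na(key)) NA_character_ else key,
                                accuracy = acc,
                                stringsAsFactors = FALSE)
    }
    per <- do.call(rbind, rows)
    ident <- sum(per$accuracy * per$length) / sum(per$length)
    # true pairings recovered: a reported antibody group whose LC, Fd and
    # Fc/2 members are the assemblies of this antibody's truth chains
    # (matched by nearest subunit mass, the same link the pipeline uses)
    ab <- ch$antibodies
    rec <- logical(nrow(ab))
    if (nrow(result$groups) > 0 && length(result$sequences) > 0) {
        for (i in seq_len(nrow(ab))) {
            want <- c(keyOfChain[[ab$lc[i]]], keyOfChain[[ab$fd[i]]],
                      keyOfChain[[ab$fc2[i]]])
            if (anyNA(want)) next
            for (g in seq_len(nrow(result$groups))) {
                gr <- result$groups[g, ]
                if (identical(gr$lc, want[1]) && identical(gr$fd, want[2]) &&
                    identical(gr$fc2, want[3])) {
                    rec[i] <- TRUE; break
                }
            }
        }
    }
    list(perSubunit = per, identity = ident,
         pairingsRecovered = sum(rec), pairingsTrue = nrow(ab))
}
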
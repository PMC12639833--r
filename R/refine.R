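## Post-assembly refinement: homology-style correction of isobaric errors
## (N vs GG, SL vs TV, swapped residues) by consensus over the de novo
## reads mapped back onto the assembled sequence, and Ile/Leu resolution
## from EThcD w-ion evidence.

.letters1 <- function(tokens) substr(tokens, 1L, 1L)
.lString <- function(tokens) chartr("I", "L", paste(.letters1(tokens), collapse = ""))

#' Correct isobaric assembly errors by read consensus
#'
#' Scans the assembled sequence for segments containing at least two
#' residues with low local confidence, anchors de novo reads to the
#' segment by exact flanking matches, and collects the residues each read
#' places between the flanks as candidate rewrites.  A rewrite is accepted
#' when it is strictly isobaric with the current segment (mass preserved to
#' 1e-6 Da), is supported by a consensus of at least \code{minSupport}
#' reads forming more than half of all mapped reads, and improves the
#' segment's mean local confidence.  Conflicting equally supported rewrites
#' leave the segment unchanged and flagged.  Up to \code{topK} candidate
#' sequences (the fully corrected sequence plus leave-one-out variants) are
#' returned ranked by total local confidence.
#'
#' @param tokens assembled residue tokens (Leu-space)
#' @param confidence per-residue local confidence of the realized path
#'   (source-read confidence, not the accumulated graph confidence)
#' @param peptides the filtered \linkS4class{DeNovoPeptideSet} (Leu-space)
#' @param masses per-residue masses of \code{tokens} (computed if NULL)
#' @param lowConf low-confidence threshold (default 0.5)
#' @param flank flanking anchor length (default 4)
#' @param maxSegment longest replaced segment (default 8)
#' @param minSupport minimum supporting reads for a rewrite (default 2)
#' @param topK candidate sequences returned (default 5)
#' @param table a \code{\link{residueTable}}
#' @return list with \code{tokens}, \code{confidence}, \code{masses} (the
#'   corrected primary sequence), \code{log} (one row per examined
#'   segment: position, original, replacement, support, decision) and
#'   \code{candidates} (ranked alternative sequences)
#' @export
spiderCorrect <- function(tokens, confidence, peptides, masses = NULL,
                          lowConf = 0.5, flank = 4L, maxSegment = 8L,
                          minSupport = 2L, topK = 5L,
                          table = residueTable()) {
    if (is.null(masses)) masses <- tokenMasses(tokens, table)
    orig <- list(tokens = tokens, masses = masses, confidence = confidence)
    pepStr <- vapply(peptides@residues, .lString, character(1))
    log <- list()
    applied <- list()

    low <- which(confidence < lowConf)
    if (length(low) >= 2L) {
        # cluster low positions with gaps <= 2 into candidate segments
        cl <- cumsum(c(1L, diff(low) > 3L))
        segs <- lapply(split(low, cl), range)
        segs <- Filter(function(s) sum(low >= s[1] & low <= s[2]) >= 2L, segs)
        # right-to-left so earlier indices stay valid after length changes
        segs <- segs[order(-vapply(segs, `[[`, numeric(1), 1L))]
        for (sg in segs) {
            s <- sg[1]; e <- sg[2]
            if (e - s + 1L > maxSegment) next
            if (s - flank < 1L || e + flank > length(tokens)) {
                log[[length(log) + 1L]] <- data.frame(
                    pos = s, original = paste(tokens[s:e], collapse = ""),
                    replacement = NA, support = 0L,
                    decision = "no-flank", stringsAsFactors = FALSE)
                next
            }
            lf <- .lString(tokens[(s - flank):(s - 1L)])
            rf <- .lString(tokens[(e + 1L):(e + flank)])
            votes <- list()
            for (pi in seq_along(pepStr)) {
                p <- pepStr[pi]
                occ <- gregexpr(lf, p, fixed = TRUE)[[1]]
                if (occ[1] == -1L) next
                for (q in occ) {
                    midFrom <- q + flank
                    # replacement length 0..maxSegment
                    for (midLen in 0:maxSegment) {
                        q2 <- midFrom + midLen
                        if (q2 + flank - 1L > nchar(p)) break
                        if (substr(p, q2, q2 + flank - 1L) == rf) {
                            mid <- if (midLen == 0L) integer(0) else
                                midFrom:(q2 - 1L)
                            votes[[length(votes) + 1L]] <- list(
                                repl = paste(peptides@residues[[pi]][mid],
                                             collapse = ""),
                                replTokens = peptides@residues[[pi]][mid],
                                replMass = peptides@residueMass[[pi]][mid],
                                conf = if (midLen == 0L) 1 else
                                    mean(peptides@confidence[[pi]][mid]))
                            break
                        }
                    }
                }
            }
            curStr <- paste(tokens[s:e], collapse = "")
            curMass <- sum(masses[s:e])
            if (length(votes) == 0L) {
                log[[length(log) + 1L]] <- data.frame(
                    pos = s, original = curStr, replacement = NA,
                    support = 0L, decision = "no-reads",
                    stringsAsFactors = FALSE)
                next
            }
            replStr <- vapply(votes, `[[`, character(1), "repl")
            tab <- sort(table(replStr), decreasing = TRUE)
            alt <- tab[names(tab) != curStr]
            decision <- "unchanged"; repl <- NA_character_; support <- 0L
            if (length(alt) > 0L) {
                top <- names(alt)[1]; support <- as.integer(alt[1])
                tied <- sum(alt == alt[1]) > 1L
                v <- votes[[match(top, replStr)]]
                isobaric <- abs(sum(v$replMass) - curMass) < 1e-6
                confGain <- mean(vapply(
                    votes[replStr == top], `[[`, numeric(1), "conf")) >
                    mean(confidence[s:e])
                if (tied && support >= minSupport) decision <- "ambiguous"
                else if (support >= minSupport &&
                         support > length(votes) / 2 &&
                         isobaric && confGain) {
                    decision <- "corrected"; repl <- top
                    newConf <- rep(mean(vapply(votes[replStr == top], `[[`,
                                               numeric(1), "conf")),
                                   length(v$replTokens))
                    applied[[length(applied) + 1L]] <-
                        list(s = s, e = e, v = v, newConf = newConf)
                    tokens <- c(tokens[seq_len(s - 1L)], v$replTokens,
                                tokens[seq.int(e + 1L, length(tokens))])
                    masses <- c(masses[seq_len(s - 1L)], v$replMass,
                                masses[seq.int(e + 1L, length(masses))])
                    confidence <- c(confidence[seq_len(s - 1L)], newConf,
                                    confidence[seq.int(e + 1L,
                                                       length(confidence))])
                }
            }
            log[[length(log) + 1L]] <- data.frame(
                pos = s, original = curStr, replacement = repl,
                support = support, decision = decision,
                stringsAsFactors = FALSE)
        }
    }
    # candidate sequences: the fully corrected primary plus leave-one-out
    # variants (corrections were applied right-to-left, so replaying any
    # subset in the same order from the original tokens is coordinate-safe),
    # ranked by mean local confidence
    replay <- function(skip) {
        tk <- orig$tokens; ms <- orig$masses; cf <- orig$confidence
        for (k in seq_along(applied)) {
            if (k == skip) next
            a <- applied[[k]]
            tk <- c(tk[seq_len(a$s - 1L)], a$v$replTokens,
                    tk[seq.int(a$e + 1L, length(tk))])
            ms <- c(ms[seq_len(a$s - 1L)], a$v$replMass,
                    ms[seq.int(a$e + 1L, length(ms))])
            cf <- c(cf[seq_len(a$s - 1L)], a$newConf,
                    cf[seq.int(a$e + 1L, length(cf))])
        }
        list(tokens = tk, confidence = cf, masses = ms,
             sequence = paste(tk, collapse = ""))
    }
    cands <- list(list(tokens = tokens, confidence = confidence,
                       masses = masses,
                       sequence = paste(tokens, collapse = "")))
    if (length(applied) > 0L)
        for (k in seq_along(applied))
            cands[[length(cands) + 1L]] <- replay(k)
    cands <- cands[!duplicated(vapply(cands, `[[`, character(1), "sequence"))]
    if (length(cands) > 1L) {
        mc <- vapply(cands, function(c) mean(c$confidence), numeric(1))
        cands <- cands[order(-mc)]
        # the consensus-corrected sequence stays primary; variants follow
        cands <- cands[seq_len(min(topK, length(cands)))]
    }
    list(tokens = tokens, confidence = confidence,
         masses = masses, sequence = paste(tokens, collapse = ""),
         log = if (length(log)) do.call(rbind, log) else
             data.frame(pos = integer(0)),
         candidates = cands)
}

#' Resolve Ile/Leu from w-ion evidence
#'
#' Assembly emits Leu at every I/L position.  Every EThcD read carrying
#' w-ion evidence is mapped onto the sequence by exact Leu-space substring
#' match; at each mapped L position the read votes for Ile or Leu and a
#' strict majority sets the residue.  Positions with no evidence or a tie
#' stay Leu and are flagged low-confidence.
#'
#' @param tokens assembled residue tokens (Leu-space)
#' @param peptides the filtered \linkS4class{DeNovoPeptideSet} with w-ion
#'   evidence
#' @return list with \code{tokens} (I/L assigned), \code{flagged}
#'   (positions left Leu without strict-majority evidence) and
#'   \code{votes} (per-position I and L counts)
#' @export
resolveIleLeu <- function(tokens, peptides) {
    L <- length(tokens)
    seqStr <- .lString(tokens)
    vI <- vL <- integer(L)
    use <- which(peptides@mode == "EThcD" &
                 vapply(peptides@wIon, function(w) any(w != ""), logical(1)))
    for (pi in use) {
        p <- .lString(peptides@residues[[pi]])
        occ <- gregexpr(p, seqStr, fixed = TRUE)[[1]]
        if (occ[1] == -1L) next
        w <- peptides@wIon[[pi]]
        ev <- which(w != "")
        for (q in occ) {
            pos <- q + ev - 1L
            isI <- w[ev] == "I"
            vI[pos[isI]] <- vI[pos[isI]] + 1L
            vL[pos[!isI]] <- vL[pos[!isI]] + 1L
        }
    }
    isL <- .letters1(tokens) == "L"
    flagged <- integer(0)
    for (p in which(isL)) {
        if (vI[p] > vL[p]) tokens[p] <- sub("^L", "I", tokens[p])
        else if (vI[p] == vL[p] && vI[p] + vL[p] == 0L)
            flagged <- c(flagged, p)
        else if (vI[p] == vL[p]) flagged <- c(flagged, p)
    }
    list(tokens = tokens, flagged = flagged,
         votes = data.frame(pos = seq_len(L), I = vI, L = vL))
}

#' Refine an assembled subunit candidate
#'
#' Applies \code{\link{spiderCorrect}} followed by
#' \code{\link{resolveIleLeu}} to the winning assembly candidate.
#'
#' @param candidate a candidate from \code{\link{sequenceSubunit}}
#' @param peptides the filtered \linkS4class{DeNovoPeptideSet}
#' @param lowConf,flank,minSupport,topK see \code{\link{spiderCorrect}}
#' @param table a \code{\link{residueTable}}
#' @return the candidate with refined \code{tokens}, \code{sequence},
#'   \code{mass} (vector \code{massVec} updated, total preserved),
#'   plus \code{refineLog} and \code{ileLeuFlagged}
#' @export
refineCandidate <- function(candidate, peptides, lowConf = 0.5, flank = 4L,
                            minSupport = 2L, topK = 5L,
                            table = residueTable()) {
    sc <- spiderCorrect(candidate$tokens, candidate$local, peptides,
                        masses = candidate$mass, lowConf = lowConf,
                        flank = flank, minSupport = minSupport,
                        topK = topK, table = table)
    il <- resolveIleLeu(sc$tokens, peptides)
    candidate$tokens <- il$tokens
    candidate$mass <- sc$masses
    candidate$local <- sc$confidence
    candidate$sequence <- paste(il$tokens, collapse = "")
    candidate$refineLog <- sc$log
    candidate$ileLeuFlagged <- il$flagged
    candidate
}
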
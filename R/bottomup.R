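## Bottom-up de novo peptide processing: quality filtering, the isobaric
## mass-block overlap graph, positional confidence accumulation, and
## terminus classification into the seven start/end classes.

#' Construct a DeNovoPeptideSet
#'
#' @param sequence character vector of peptide strings (inline modification
#'   deltas allowed, e.g. \code{"Q(-17.03)SVLTQ"})
#' @param confidence list of per-residue local confidence vectors in [0, 1];
#'   defaults to 1 everywhere
#' @param alc average local confidence per peptide; defaults to the mean of
#'   the local confidences
#' @param mode fragmentation mode per peptide (\code{"HCD"}/\code{"EThcD"})
#' @param spectrumId spectrum identifiers
#' @param wIon list of per-residue w-ion evidence (\code{"I"}, \code{"L"} or
#'   \code{""}); defaults to no evidence
#' @param table a \code{\link{residueTable}}
#' @return a \linkS4class{DeNovoPeptideSet}
#' @export
deNovoPeptideSet <- function(sequence, confidence = NULL, alc = NULL,
                             mode = NULL, spectrumId = NULL, wIon = NULL,
                             table = residueTable()) {
    n <- length(sequence)
    parsed <- lapply(sequence, parsePeptide, table = table)
    residues <- lapply(parsed, `[[`, "tokens")
    residueMass <- lapply(parsed, `[[`, "mass")
    if (is.null(confidence))
        confidence <- lapply(residues, function(r) rep(1, length(r)))
    if (is.null(alc)) alc <- vapply(confidence, mean, numeric(1))
    if (is.null(mode)) mode <- rep("HCD", n)
    if (is.null(spectrumId)) spectrumId <- sprintf("S%06d", seq_len(n))
    if (is.null(wIon))
        wIon <- lapply(residues, function(r) rep("", length(r)))
    new("DeNovoPeptideSet", sequence = sequence, residues = residues,
        residueMass = residueMass, confidence = confidence, alc = alc,
        mode = mode, spectrumId = spectrumId, wIon = wIon)
}

#' Filter de novo peptides on ALC and low-confidence runs
#'
#' Keeps peptides whose ALC exceeds \code{minAlc} and whose longest run of
#' consecutive residues with local confidence below \code{lowConfThreshold}
#' does not exceed \code{maxLowConfRun}.
#'
#' @param peptides a \linkS4class{DeNovoPeptideSet}
#' @param minAlc ALC threshold, exclusive (default 0.7)
#' @param maxLowConfRun longest tolerated unconfident run (default 4)
#' @param lowConfThreshold local confidence below which a residue counts as
#'   unconfident (default 0.5)
#' @return the filtered \linkS4class{DeNovoPeptideSet}
#' @export
filterPeptides <- function(peptides, minAlc = 0.7, maxLowConfRun = 4L,
                           lowConfThreshold = 0.5) {
    keep <- vapply(seq_along(peptides@alc), function(i) {
        if (peptides@alc[i] <= minAlc) return(FALSE)
        low <- peptides@confidence[[i]] < lowConfThreshold
        if (!any(low)) return(TRUE)
        r <- rle(low)
        max(r$lengths[r$values]) <= maxLowConfRun
    }, logical(1))
    peptides[keep]
}

#' Convert every Ile to Leu
#'
#' Ile and Leu share one residue mass; sequencing is carried out in
#' Leu-space and individual positions are resolved afterwards from w-ion
#' evidence (\code{\link{resolveIleLeu}}).
#'
#' @param peptides a \linkS4class{DeNovoPeptideSet}
#' @return the peptide set with every I residue rewritten as L
#' @export
convertIleToLeu <- function(peptides) {
    for (i in seq_along(peptides@sequence)) {
        isI <- substr(peptides@residues[[i]], 1L, 1L) == "I"
        if (any(isI)) {
            peptides@residues[[i]][isI] <-
                sub("^I", "L", peptides@residues[[i]][isI])
            peptides@sequence[i] <- paste(peptides@residues[[i]], collapse = "")
        }
    }
    peptides
}

#' Build the mass-block overlap graph
#'
#' Draws a directed edge u -> v whenever the maximal suffix(u)/prefix(v)
#' overlap decomposes into at least \code{minBlocks} isobaric mass blocks
#' (\code{\link{alignMassBlocks}}) and v extends beyond the overlap.
#' Modifications participate through the per-residue masses, so
#' post-translational modifications are preserved across the graph.
#'
#' @param peptides a filtered \linkS4class{DeNovoPeptideSet}
#' @param minBlocks minimum mass blocks per edge (default 3)
#' @param accumulate also accumulate per-residue confidence across
#'   overlapping neighbours (default TRUE; see
#'   \code{\link{accumulateConfidence}})
#' @return an \linkS4class{OverlapGraph}
#' @export
buildOverlapGraph <- function(peptides, minBlocks = 3L, accumulate = TRUE) {
    res <- cpp_build_graph(peptides@residueMass, peptides@confidence,
                           peptides@alc, as.integer(minBlocks), accumulate)
    edges <- data.frame(from = res$from, to = res$to, aStart = res$aStart,
                        bConsumed = res$bConsumed, nBlocks = res$nBlocks)
    new("OverlapGraph", peptides = peptides, edges = edges,
        accConfidence = res$acc, minBlocks = as.integer(minBlocks))
}

#' Accumulate positional confidence across overlapping peptides
#'
#' For every peptide P, the local confidence of each neighbour inside the
#' overlapped region is accumulated into P's positions: residues aligned by
#' a one-to-one mass block contribute the neighbour's positional score,
#' residues inside a longer block (where positions are ambiguous) contribute
#' the neighbour's ALC.  The accumulated score of a residue is
#' \code{min(1, base + mean(contributions))}; it is computed from the
#' neighbours' original scores, so the result is order-independent and never
#' below the original local confidence.
#'
#' @param graph an \linkS4class{OverlapGraph}
#' @return the graph with updated \code{accConfidence}
#' @export
accumulateConfidence <- function(graph) {
    res <- cpp_build_graph(graph@peptides@residueMass,
                           graph@peptides@confidence, graph@peptides@alc,
                           graph@minBlocks, TRUE)
    graph@accConfidence <- res$acc
    graph
}

.TERMINUS_CLASSES <- c("LC-START", "LC-END", "Fd-START", "Fd-END",
                       "Fc/2-START", "Fc/2-END", "OTHER")

#' Terminal consensus motif profiles
#'
#' Loads the shipped consensus motifs of antibody chain N and C termini
#' used by the default terminus classifier: several alternative motifs per
#' class (light chain starts such as DIQMTQSP / EIVLTQSP / QSVLTQPP, the
#' Fc/2 start GPSVFLFP, the hinge-proximal Fd end, ...).  The profile file
#' is plain text (class, motif) and can be replaced to retarget the
#' classifier.
#'
#' @param file optional alternative profile file
#' @return data.frame with columns \code{class} and \code{motif}
#' @export
terminusProfiles <- function(file = NULL) {
    if (is.null(file))
        file <- system.file("extdata", "terminus_motifs.tsv",
                            package = "AbSeqMS", mustWork = TRUE)
    pr <- utils::read.table(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    stopifnot(all(c("class", "motif") %in% names(pr)))
    pr
}

.motifScore <- function(pepLetters, motif, fromEnd, minLen = 5L) {
    m <- strsplit(chartr("I", "L", motif), "")[[1]]
    k <- min(length(pepLetters), length(m))
    if (k < minLen) return(0)
    if (fromEnd) {
        a <- pepLetters[(length(pepLetters) - k + 1L):length(pepLetters)]
        b <- m[(length(m) - k + 1L):length(m)]
    } else {
        a <- pepLetters[1:k]
        b <- m[1:k]
    }
    mean(a == b)
}

#' Classify peptides into terminus classes
#'
#' Pluggable classifier deciding whether a peptide can start or end an
#' antibody subunit.  The default implementation scores the peptide's
#' prefix (respectively suffix) against shipped consensus motifs of the six
#' terminal classes (LC-START, LC-END, Fd-START, Fd-END, Fc/2-START,
#' Fc/2-END) and returns OTHER when no motif reaches the score floor.
#' Matching is done in Leu-space, so I/L differences never break a motif.
#'
#' @param peptides a \linkS4class{DeNovoPeptideSet}
#' @param profiles motif table from \code{\link{terminusProfiles}}, or any
#'   data.frame with columns \code{class} and \code{motif}
#' @param scoreFloor minimum identity fraction over the compared window
#'   (default 0.8, i.e. at most one mismatch over an 8-residue motif)
#' @param minLen shortest peptide/motif window considered (default 5)
#' @return factor of the seven classes, one per peptide
#' @export
classifyTerminus <- function(peptides, profiles = terminusProfiles(),
                             scoreFloor = 0.8, minLen = 5L) {
    startP <- profiles[grepl("START$", profiles$class), ]
    endP <- profiles[grepl("END$", profiles$class), ]
    out <- character(length(peptides))
    for (i in seq_along(out)) {
        letters <- chartr("I", "L", substr(peptides@residues[[i]], 1L, 1L))
        if (length(letters) < minLen) { out[i] <- "OTHER"; next }
        sScore <- vapply(startP$motif, .motifScore, numeric(1),
                         pepLetters = letters, fromEnd = FALSE, minLen = minLen)
        eScore <- vapply(endP$motif, .motifScore, numeric(1),
                         pepLetters = letters, fromEnd = TRUE, minLen = minLen)
        best <- max(c(sScore, eScore, 0))
        if (best < scoreFloor) { out[i] <- "OTHER"; next }
        if (length(sScore) && max(sScore) >= max(c(eScore, 0)))
            out[i] <- startP$class[which.max(sScore)]
        else
            out[i] <- endP$class[which.max(eScore)]
    }
    factor(out, levels = .TERMINUS_CLASSES)
}

#' Start/end peptide sets per subunit type
#'
#' @param classes factor from \code{\link{classifyTerminus}}
#' @return list with one element per subunit type (\code{LC}, \code{Fd},
#'   \code{Fc2}), each holding integer vectors \code{start} and \code{end}
#' @export
terminusSets <- function(classes) {
    list(
        LC = list(start = which(classes == "LC-START"),
                  end = which(classes == "LC-END")),
        Fd = list(start = which(classes == "Fd-START"),
                  end = which(classes == "Fd-END")),
        Fc2 = list(start = which(classes == "Fc/2-START"),
                   end = which(classes == "Fc/2-END")))
}
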
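## Evaluation utilities: residue-level sequencing accuracy against a known
## truth and per-residue coverage reporting.

#' Residue-level sequencing accuracy
#'
#' Number of correctly identified residues divided by the length of the
#' sequenced candidate.  Equal-length sequences are compared positionally;
#' otherwise the sequences are aligned globally (unit match/mismatch,
#' linear unit gap cost) and matched positions are counted.
#'
#' @param candidate sequenced residue string (or token vector)
#' @param truth ground-truth residue string (or token vector)
#' @return accuracy fraction in [0, 1]
#' @export
residueAccuracy <- function(candidate, truth) {
    if (length(candidate) > 1L) candidate <- paste(substr(candidate, 1, 1),
                                                   collapse = "")
    if (length(truth) > 1L) truth <- paste(substr(truth, 1, 1), collapse = "")
    candidate <- gsub("\\([^)]*\\)", "", candidate)
    truth <- gsub("\\([^)]*\\)", "", truth)
    if (nchar(candidate) == 0L) stop("empty candidate sequence")
    if (nchar(candidate) == nchar(truth)) {
        a <- strsplit(candidate, "")[[1]]
        b <- strsplit(truth, "")[[1]]
        return(mean(a == b))
    }
    letters <- sort(unique(c(strsplit(candidate, "")[[1]],
                             strsplit(truth, "")[[1]])))
    m <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- 1
    aln <- Biostrings::pairwiseAlignment(candidate, truth,
        substitutionMatrix = m, gapOpening = 0, gapExtension = 1,
        type = "global")
    Biostrings::nmatch(aln) / nchar(candidate)
}

#' Per-residue coverage report for a sequenced subunit
#'
#' Maps the bottom-up reads onto the candidate by exact Leu-space substring
#' match and reports per-residue read depth, the confidence tier of each
#' residue (best mapped local confidence: >0.95, >0.85, or at most 0.85),
#' and the matched middle-down c/z fragmentation sites.
#'
#' @param candidate residue token vector (or string)
#' @param peptides a \linkS4class{DeNovoPeptideSet}
#' @param fms the subunit's \linkS4class{FragmentMassSet} (or NULL)
#' @param table a \code{\link{residueTable}}
#' @return list with \code{depth} (integer per residue), \code{tier}
#'   (factor: \code{">95"}, \code{">85"}, \code{"<=85"}), \code{cSites},
#'   \code{zSites} (logical per cleavage site) and \code{mdCoverage}
#' @export
coverageReport <- function(candidate, peptides, fms = NULL,
                           table = residueTable()) {
    if (is.character(candidate) && length(candidate) == 1L)
        candidate <- parsePeptide(candidate, table)$tokens
    L <- length(candidate)
    seqStr <- .lString(candidate)
    depth <- integer(L)
    bestConf <- numeric(L)
    pepStr <- vapply(peptides@residues, .lString, character(1))
    for (pi in seq_along(pepStr)) {
        occ <- gregexpr(pepStr[pi], seqStr, fixed = TRUE)[[1]]
        if (occ[1] == -1L) next
        n <- nchar(pepStr[pi])
        for (q in occ) {
            idx <- q:(q + n - 1L)
            depth[idx] <- depth[idx] + 1L
            bestConf[idx] <- pmax(bestConf[idx], peptides@confidence[[pi]])
        }
    }
    tier <- cut(bestConf, c(-Inf, 0.85, 0.95, Inf),
                labels = c("<=85", ">85", ">95"))
    sites <- NULL; cov <- NA_real_
    if (!is.null(fms)) {
        pp <- list(tokens = candidate,
                   mass = tokenMasses(candidate, table),
                   letters = substr(candidate, 1, 1))
        sites <- matchedSites(pp, fms, table)
        cov <- mdCoverage(pp, fms, table)
    }
    list(depth = depth, tier = tier,
         cSites = sites$cSites, zSites = sites$zSites, mdCoverage = cov)
}
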
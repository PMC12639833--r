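#' @import methods
NULL

#' Set of bottom-up de novo peptide reads
#'
#' Container for de novo peptide-spectrum matches as exported by a bottom-up
#' de novo sequencer: the residue string (with inline modification
#' annotations such as \code{"Q(-17.03)"}), per-residue local confidence,
#' the average local confidence (ALC), the fragmentation mode, a spectrum
#' identifier, and optional per-residue w-ion evidence (\code{"I"},
#' \code{"L"} or \code{""}) from EThcD spectra.
#'
#' @slot sequence display string per peptide (tokens pasted)
#' @slot residues list of character vectors, one residue token per element
#' @slot residueMass list of numeric vectors, monoisotopic mass per residue
#'   including any modification delta
#' @slot confidence list of numeric vectors in [0, 1], one per residue
#' @slot alc numeric vector, average local confidence in [0, 1]
#' @slot mode character vector, \code{"HCD"} or \code{"EThcD"}
#' @slot spectrumId character vector
#' @slot wIon list of character vectors (\code{"I"}, \code{"L"} or \code{""})
#'
#' @exportClass DeNovoPeptideSet
setClass("DeNovoPeptideSet",
    representation(
        sequence = "character",
        residues = "list",
        residueMass = "list",
        confidence = "list",
        alc = "numeric",
        mode = "character",
        spectrumId = "character",
        wIon = "list"
    )
)

setValidity("DeNovoPeptideSet", function(object) {
    n <- length(object@sequence)
    lens <- c(length(object@residues), length(object@residueMass),
              length(object@confidence), length(object@alc),
              length(object@mode), length(object@spectrumId),
              length(object@wIon))
    if (any(lens != n))
        return("all slots must have one entry per peptide")
    for (i in seq_len(n)) {
        L <- length(object@residues[[i]])
        if (L == 0L) return("empty peptide")
        if (length(object@residueMass[[i]]) != L ||
            length(object@confidence[[i]]) != L ||
            length(object@wIon[[i]]) != L)
            return(sprintf("peptide %d: per-residue slots disagree in length", i))
        if (any(object@confidence[[i]] < 0 | object@confidence[[i]] > 1))
            return(sprintf("peptide %d: confidence outside [0, 1]", i))
    }
    if (any(object@alc < 0 | object@alc > 1)) return("ALC outside [0, 1]")
    TRUE
})

#' Aggregated middle-down fragment masses for one subunit precursor
#'
#' Neutral fragment masses (ETD c and z ions, deconvoluted upstream) pooled
#' over all runs and precursors of one subunit, together with the derived
#' neutral prefix residue masses (PRMs: every fragment read as a c ion) and
#' suffix residue masses (SRMs: every fragment read as a z ion).
#'
#' @slot precursorMass neutral monoisotopic precursor (subunit) mass in Da
#' @slot fragmentMass sorted neutral fragment masses in Da
#' @slot intensity fragment intensities (same order)
#' @slot prm fragment masses minus the c-ion offset, sorted
#' @slot srm fragment masses minus the z-ion offset, sorted
#' @slot tolerancePpm match tolerance in ppm
#'
#' @exportClass FragmentMassSet
setClass("FragmentMassSet",
    representation(
        precursorMass = "numeric",
        fragmentMass = "numeric",
        intensity = "numeric",
        prm = "numeric",
        srm = "numeric",
        tolerancePpm = "numeric"
    )
)

setValidity("FragmentMassSet", function(object) {
    if (length(object@precursorMass) != 1L || object@precursorMass <= 0)
        return("precursorMass must be a single positive number")
    if (length(object@fragmentMass) != length(object@intensity))
        return("fragmentMass and intensity lengths differ")
    if (any(object@fragmentMass <= 0)) return("fragment masses must be positive")
    if (is.unsorted(object@fragmentMass)) return("fragmentMass must be sorted")
    if (is.unsorted(object@prm) || is.unsorted(object@srm))
        return("prm and srm lists must be sorted")
    TRUE
})

#' Bidirectional mass-block overlap graph over de novo peptides
#'
#' Nodes are peptides; a directed edge u -> v means the maximal
#' suffix(u)/prefix(v) overlap decomposes into at least \code{minBlocks}
#' isobaric mass blocks and v contributes residues beyond the overlap.
#' \code{accConfidence} holds the per-residue confidence after accumulation
#' over overlapping neighbours.
#'
#' @slot peptides a \linkS4class{DeNovoPeptideSet}
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{aStart}
#'   (first overlapped residue of u), \code{bConsumed} (residues of v inside
#'   the overlap) and \code{nBlocks}
#' @slot accConfidence list of numeric vectors, accumulated confidence
#' @slot minBlocks minimum mass blocks per edge
#'
#' @exportClass OverlapGraph
setClass("OverlapGraph",
    representation(
        peptides = "DeNovoPeptideSet",
        edges = "data.frame",
        accConfidence = "list",
        minBlocks = "integer"
    )
)

setValidity("OverlapGraph", function(object) {
    n <- length(object@peptides@sequence)
    ed <- object@edges
    need <- c("from", "to", "aStart", "bConsumed", "nBlocks")
    if (!all(need %in% names(ed))) return("edges lacks required columns")
    if (nrow(ed) > 0) {
        if (any(ed$from < 1 | ed$from > n | ed$to < 1 | ed$to > n))
            return("edge endpoints out of range")
        if (any(ed$nBlocks < object@minBlocks))
            return("edge with fewer than minBlocks blocks")
    }
    if (length(object@accConfidence) != n)
        return("accConfidence must have one vector per peptide")
    for (i in seq_len(n)) {
        if (any(object@accConfidence[[i]] + 1e-9 < object@peptides@confidence[[i]]))
            return("accumulated confidence below original local confidence")
    }
    TRUE
})

#' Deconvoluted proteoform masses with supporting features
#'
#' One row per reported neutral mass; each mass is backed by a set of
#' (m/z window, RT window, charge) features with a run of consecutive
#' charges.
#'
#' @slot table data.frame with columns \code{mass}, \code{mode}
#'   (\code{"monoisotopic"} or \code{"average"}), \code{abundance} and
#'   \code{nFeatures}
#' @slot features list (one per row) of data.frames with columns \code{z},
#'   \code{mzLo}, \code{mzHi}, \code{rtLo}, \code{rtHi}, \code{intensity},
#'   \code{mzApex}, \code{rtApex}
#'
#' @exportClass ProteoformSet
setClass("ProteoformSet",
    representation(table = "data.frame", features = "list")
)

setValidity("ProteoformSet", function(object) {
    tb <- object@table
    need <- c("mass", "mode", "abundance", "nFeatures")
    if (!all(need %in% names(tb))) return("table lacks required columns")
    if (length(object@features) != nrow(tb))
        return("one feature set per proteoform required")
    if (nrow(tb) > 0) {
        if (any(tb$mass <= 0)) return("masses must be positive")
        if (sum(tb$abundance) > 1 + 1e-6)
            return("relative abundances must sum to <= 1")
        if (!all(tb$mode %in% c("monoisotopic", "average")))
            return("mode must be monoisotopic or average")
    }
    TRUE
})

#' @describeIn DeNovoPeptideSet number of peptides
#' @param x a \code{DeNovoPeptideSet}
#' @export
setMethod("length", "DeNovoPeptideSet", function(x) length(x@sequence))

#' Subset a DeNovoPeptideSet
#' @param x a \code{DeNovoPeptideSet}
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "DeNovoPeptideSet", function(x, i, j, ..., drop = TRUE) {
    new("DeNovoPeptideSet",
        sequence = x@sequence[i], residues = x@residues[i],
        residueMass = x@residueMass[i], confidence = x@confidence[i],
        alc = x@alc[i], mode = x@mode[i], spectrumId = x@spectrumId[i],
        wIon = x@wIon[i])
})

setMethod("show", "DeNovoPeptideSet", function(object) {
    n <- length(object)
    cat("DeNovoPeptideSet with", n, "peptides\n")
    if (n > 0) {
        cat("  length range:", min(lengths(object@residues)), "-",
            max(lengths(object@residues)), "residues\n")
        cat("  ALC range:", sprintf("%.2f - %.2f", min(object@alc),
            max(object@alc)), "\n")
        cat("  modes:", paste(names(table(object@mode)), collapse = ", "), "\n")
    }
})

setMethod("show", "FragmentMassSet", function(object) {
    cat("FragmentMassSet: precursor", sprintf("%.3f", object@precursorMass),
        "Da,", length(object@fragmentMass), "fragments, tolerance",
        object@tolerancePpm, "ppm\n")
})

setMethod("show", "OverlapGraph", function(object) {
    cat("OverlapGraph:", length(object@peptides), "peptides,",
        nrow(object@edges), "edges (>=", object@minBlocks, "mass blocks)\n")
})

setMethod("show", "ProteoformSet", function(object) {
    cat("ProteoformSet with", nrow(object@table), "proteoform masses\n")
    if (nrow(object@table) > 0) {
        tb <- object@table[order(-object@table$abundance), ]
        print(utils::head(tb, 8), row.names = FALSE)
    }
})

#' @rdname accessors
#' @param object an AbSeqMS S4 object
#' @export
setGeneric("peptideSequences", function(object) standardGeneric("peptideSequences"))
#' @rdname accessors
#' @export
setMethod("peptideSequences", "DeNovoPeptideSet", function(object) object@sequence)

#' @rdname accessors
#' @export
setGeneric("alcScores", function(object) standardGeneric("alcScores"))
#' @rdname accessors
#' @export
setMethod("alcScores", "DeNovoPeptideSet", function(object) object@alc)

#' @rdname accessors
#' @export
setGeneric("localConfidence", function(object) standardGeneric("localConfidence"))
#' @rdname accessors
#' @export
setMethod("localConfidence", "DeNovoPeptideSet", function(object) object@confidence)

#' @rdname accessors
#' @export
setGeneric("precursorMass", function(object) standardGeneric("precursorMass"))
#' @rdname accessors
#' @export
setMethod("precursorMass", "FragmentMassSet", function(object) object@precursorMass)

#' @rdname accessors
#' @export
setGeneric("fragmentMasses", function(object) standardGeneric("fragmentMasses"))
#' @rdname accessors
#' @export
setMethod("fragmentMasses", "FragmentMassSet", function(object) object@fragmentMass)

#' @rdname accessors
#' @export
setGeneric("prmList", function(object) standardGeneric("prmList"))
#' @rdname accessors
#' @export
setMethod("prmList", "FragmentMassSet", function(object) object@prm)

#' @rdname accessors
#' @export
setGeneric("srmList", function(object) standardGeneric("srmList"))
#' @rdname accessors
#' @export
setMethod("srmList", "FragmentMassSet", function(object) object@srm)

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setMethod("graphEdges", "OverlapGraph", function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("graphPeptides", function(object) standardGeneric("graphPeptides"))
#' @rdname accessors
#' @export
setMethod("graphPeptides", "OverlapGraph", function(object) object@peptides)

#' @rdname accessors
#' @export
setGeneric("accumulatedConfidence", function(object) standardGeneric("accumulatedConfidence"))
#' @rdname accessors
#' @export
setMethod("accumulatedConfidence", "OverlapGraph", function(object) object@accConfidence)

#' @rdname accessors
#' @export
setGeneric("proteoformTable", function(object) standardGeneric("proteoformTable"))
#' @rdname accessors
#' @export
setMethod("proteoformTable", "ProteoformSet", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("proteoformFeatures", function(object) standardGeneric("proteoformFeatures"))
#' @rdname accessors
#' @export
setMethod("proteoformFeatures", "ProteoformSet", function(object) object@features)
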
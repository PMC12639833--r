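## Residue-mass arithmetic, modification handling, isobaric mass blocks
## and ppm utilities.  Everything downstream (overlap graph, DP assembly,
## fragment matching, pairing) is built on these primitives.

# Monoisotopic residue masses (Da), elemental-composition precision so that
# isobaric segments (N vs GG, Q vs GA, SL vs TV) agree to float rounding.
.MONO <- c(
    G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
    V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
    I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
    K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
    F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295)

# Average residue masses (Da)
.AVG <- c(
    G = 57.0513, A = 71.0779, S = 87.0773, P = 97.1152, V = 99.1311,
    T = 101.1039, C = 103.1429, L = 113.1576, I = 113.1576, N = 114.1026,
    D = 115.0874, Q = 128.1292, K = 128.1723, E = 129.1140, M = 131.1961,
    H = 137.1393, F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099)

.MODS <- c(
    "Carbamidomethyl" = 57.02146372,
    "PyroGlu"         = -17.02654910,
    "Deamidation"     = 0.98401658,
    "LysLoss"         = -128.09496302)

#' Residue and modification mass table
#'
#' Returns the table of residue masses, modification deltas and physical
#' constants used throughout the package.  All 20 standard residues are
#' present; Ile and Leu share one mass.  The average-mode water constant is
#' 18.011 Da, the convention used in subunit-to-chain mass arithmetic
#' (a reduced heavy chain mass is Fd + Fc/2 minus average water); the
#' monoisotopic water mass is 18.010565 Da.  The averagine residue mass
#' (111.1254 Da) estimates the residue count of a chain from its mass.
#'
#' @param file optional plain-text override table with columns
#'   \code{name} and \code{mass} (residues as single letters, modifications
#'   by name); entries replace or extend the defaults.
#' @return a list of class \code{ResidueTable} with elements
#'   \code{residues} (named monoisotopic masses), \code{residuesAvg},
#'   \code{modifications} (named deltas) and \code{constants}.
#' @examples
#' tb <- residueTable()
#' tb$residues[["G"]]
#' @export
residueTable <- function(file = NULL) {
    tb <- list(
        residues = .MONO,
        residuesAvg = .AVG,
        modifications = .MODS,
        constants = c(
            waterMono = 18.01056468,
            waterAvg = 18.011,
            proton = 1.00727646688,
            averagineResidueMass = 111.1254,
            disulfideLossMono = 2.01565006,
            disulfideLossAvg = 2.0159,
            cIonOffset = 17.02654910,
            zIonOffset = 2.00548772))
    if (!is.null(file)) {
        ov <- utils::read.table(file, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        stopifnot(all(c("name", "mass") %in% names(ov)))
        for (i in seq_len(nrow(ov))) {
            nm <- ov$name[i]
            if (nchar(nm) == 1L) tb$residues[[nm]] <- ov$mass[i]
            else tb$modifications[[nm]] <- ov$mass[i]
        }
    }
    class(tb) <- "ResidueTable"
    tb
}

#' Parse a peptide string into residue tokens
#'
#' Accepts plain residue strings and strings with inline modification
#' deltas in parentheses, e.g. \code{"Q(-17.03)SVLTQ"} or
#' \code{"C(+57.02)PAP"}.  A printed delta is snapped to the closest known
#' modification delta within 0.01 Da so that downstream mass arithmetic
#' uses full precision.
#'
#' @param x a single peptide string
#' @param table a \code{\link{residueTable}}
#' @return list with \code{tokens} (character), \code{letters} (character),
#'   \code{mass} (numeric per-residue masses including deltas)
#' @export
parsePeptide <- function(x, table = residueTable()) {
    stopifnot(is.character(x), length(x) == 1L)
    m <- gregexpr("[A-Za-z](\\([+-]?[0-9]+\\.?[0-9]*\\))?", x)[[1]]
    toks <- regmatches(x, list(m))[[1]]
    if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(x))
        stop("cannot parse peptide string: ", x, call. = FALSE)
    letters <- toupper(substr(toks, 1L, 1L))
    unknown <- setdiff(letters, names(table$residues))
    if (length(unknown) > 0)
        stop(errorCondition(paste0("unknown residue: ", unknown[1]),
                            class = c("abseqms_unknown_residue", "error")))
    mass <- unname(table$residues[letters])
    has_mod <- nchar(toks) > 1L
    if (any(has_mod)) {
        deltas <- as.numeric(sub("^[A-Za-z]\\(([-+0-9.]+)\\)$", "\\1",
                                 toks[has_mod]))
        if (anyNA(deltas))
            stop(errorCondition(
                paste0("unknown modification token: ", toks[has_mod][is.na(deltas)][1]),
                class = c("abseqms_unknown_modification", "error")))
        snapped <- vapply(deltas, function(d) {
            i <- which.min(abs(table$modifications - d))
            if (abs(table$modifications[i] - d) < 0.01)
                unname(table$modifications[i]) else d
        }, numeric(1))
        mass[has_mod] <- mass[has_mod] + snapped
    }
    list(tokens = toks, letters = letters, mass = mass)
}

.asTokens <- function(x, table = residueTable()) {
    if (is.list(x) && !is.null(x$mass)) return(x)
    parsePeptide(x, table)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus modification deltas plus one water.  The
#' empty chain is a single water molecule.
#'
#' @param x peptide string (optionally with inline modification deltas) or
#'   the result of \code{\link{parsePeptide}}
#' @param table a \code{\link{residueTable}}
#' @param mode \code{"monoisotopic"} (default) or \code{"average"}
#' @return mass in Da
#' @examples
#' peptideMass("")        # one water
#' peptideMass("G")
#' @export
peptideMass <- function(x, table = residueTable(), mode = c("monoisotopic", "average")) {
    mode <- match.arg(mode)
    if (is.character(x) && length(x) == 1L && nchar(x) == 0L)
        return(unname(if (mode == "monoisotopic") table$constants["waterMono"]
                      else table$constants["waterAvg"]))
    p <- .asTokens(x, table)
    if (mode == "monoisotopic")
        return(sum(p$mass) + unname(table$constants["waterMono"]))
    # average mode: average residue masses, keeping (monoisotopic)
    # modification deltas -- the difference is sub-mDa per site
    base <- unname(table$residuesAvg[p$letters])
    deltas <- p$mass - unname(table$residues[p$letters])
    sum(base + deltas) + unname(table$constants["waterAvg"])
}

#' Residue masses of a token vector
#'
#' @param tokens character vector of residue tokens
#' @param table a \code{\link{residueTable}}
#' @param mode mass mode
#' @return numeric vector of per-residue masses
#' @export
tokenMasses <- function(tokens, table = residueTable(),
                        mode = c("monoisotopic", "average")) {
    mode <- match.arg(mode)
    p <- parsePeptide(paste(tokens, collapse = ""), table)
    if (mode == "monoisotopic") return(p$mass)
    base <- unname(table$residuesAvg[p$letters])
    base + (p$mass - unname(table$residues[p$letters]))
}

#' Align two peptides by isobaric mass blocks
#'
#' Finds the maximal suffix(A)/prefix(B) overlap that decomposes into
#' ordered pairs of equal-mass segments ("mass blocks") no longer than two
#' residues per side, so that isobaric differences such as N vs GG do not
#' break an overlap.  Among decompositions of the maximal overlap the one
#' with the most blocks (finest granularity) is chosen.  Block equality is
#' exact residue arithmetic (1e-6 Da), not an instrument tolerance.
#'
#' @param a,b peptide strings or \code{\link{parsePeptide}} results
#' @param minBlocks minimum number of blocks for a reported alignment
#' @param table a \code{\link{residueTable}}
#' @return \code{NULL} when no overlap qualifies, otherwise a list of class
#'   \code{MassBlockAlignment} with \code{aStart} (first overlapped residue
#'   of A), \code{bConsumed} (residues of B inside the overlap),
#'   \code{blockCount}, and \code{blocks}: a list of \code{(a =, b =)} token
#'   segments, equal in mass within exact arithmetic.
#' @examples
#' aln <- alignMassBlocks("SEQVENCE", "EGGECPEP")
#' aln$blockCount   # 3: [E | E] [N | GG] [CE | EC]
#' @export
alignMassBlocks <- function(a, b, minBlocks = 1L, table = residueTable()) {
    stopifnot(minBlocks >= 1L)
    pa <- .asTokens(a, table)
    pb <- .asTokens(b, table)
    if (length(pa$mass) == 0L || length(pb$mass) == 0L)
        stop("peptides must be non-empty")
    res <- cpp_align_blocks(pa$mass, pb$mass, as.integer(minBlocks))
    if (is.null(res)) return(NULL)
    bm <- res$blocks
    blocks <- vector("list", nrow(bm))
    ap <- res$aStart
    bp <- 1L
    for (t in seq_len(nrow(bm))) {
        la <- bm[t, 1]; lb <- bm[t, 2]
        blocks[[t]] <- list(a = pa$tokens[ap:(ap + la - 1L)],
                            b = pb$tokens[bp:(bp + lb - 1L)])
        ap <- ap + la; bp <- bp + lb
    }
    structure(list(aStart = res$aStart, bConsumed = res$bConsumed,
                   blockCount = res$blockCount, blocks = blocks),
              class = "MassBlockAlignment")
}

#' @export
print.MassBlockAlignment <- function(x, ...) {
    segs <- vapply(x$blocks, function(b) {
        a <- paste(b$a, collapse = "")
        bb <- paste(b$b, collapse = "")
        if (identical(a, bb)) sprintf("[%s]", a) else sprintf("[%s/%s]", a, bb)
    }, character(1))
    cat("MassBlockAlignment:", x$blockCount, "blocks",
        paste(segs, collapse = ""), "\n")
    invisible(x)
}

#' Signed mass deviation in parts per million
#'
#' \code{(expected - observed) / observed * 1e6}; the sign convention
#' reproduces pairing-report deltas where the calculated mass from a
#' subunit combination is compared against the observed deconvoluted mass.
#'
#' @param expected calculated mass in Da
#' @param observed observed mass in Da (must be positive)
#' @return signed ppm
#' @examples
#' ppmDelta(25383.27 + 23791.52 - 18.011, 49156.70)  # 1.6 ppm
#' @export
ppmDelta <- function(expected, observed) {
    if (any(observed <= 0)) stop("observed mass must be positive")
    (expected - observed) / observed * 1e6
}
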
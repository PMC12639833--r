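## Readers and writers for the external plain-text formats: centroid TSV,
## proteoform TSV, inclusion-list CSV, per-run fragment TSV, de novo
## peptide CSV, FASTA chains and pairing reports.

#' Read centroided intact scans from TSV
#'
#' Three-column tab-separated input: \code{rt_min}, \code{mz},
#' \code{intensity}; rows sharing one RT form one scan.
#'
#' @param file path
#' @return list of \code{\link{centroidScan}} sorted by RT
#' @export
readCentroidTSV <- function(file) {
    d <- utils::read.table(file, header = TRUE, sep = "\t")
    stopifnot(all(c("rt_min", "mz", "intensity") %in% names(d)))
    lapply(split(d, d$rt_min), function(s)
        centroidScan(s$rt_min[1], s$mz, s$intensity))
}

#' Write / read a proteoform table
#'
#' Tab-separated columns: mass, mode, abundance, n_features.
#'
#' @param pf a \linkS4class{ProteoformSet}
#' @param file path
#' @export
writeProteoformTSV <- function(pf, file) {
    tb <- proteoformTable(pf)
    utils::write.table(
        data.frame(mass = tb$mass, mode = tb$mode,
                   abundance = tb$abundance, n_features = tb$nFeatures),
        file, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname writeProteoformTSV
#' @export
readProteoformTSV <- function(file) {
    d <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    proteoformSet(d$mass, d$mode, d$abundance)
}

#' Write an inclusion list as instrument-importable CSV
#'
#' Columns: mz, rt_start, rt_end, z, parent_mass.
#'
#' @param il output of \code{\link{buildInclusionList}}
#' @param file path
#' @export
writeInclusionCSV <- function(il, file) {
    utils::write.csv(
        data.frame(mz = il$mz, rt_start = il$rtStart, rt_end = il$rtEnd,
                   z = il$z, parent_mass = il$parentMass),
        file, row.names = FALSE, quote = FALSE)
}

#' Write / read per-run middle-down fragment lists
#'
#' Tab-separated columns: precursor_mass, fragment_mass, intensity; all
#' masses neutral, in Da.
#'
#' @param run data.frame with columns precursorMass, fragMass, intensity
#' @param file path
#' @export
writeFragmentTSV <- function(run, file) {
    utils::write.table(
        data.frame(precursor_mass = run$precursorMass,
                   fragment_mass = run$fragMass,
                   intensity = run$intensity),
        file, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname writeFragmentTSV
#' @export
readFragmentTSV <- function(file) {
    d <- utils::read.table(file, header = TRUE, sep = "\t")
    data.frame(precursorMass = d$precursor_mass,
               fragMass = d$fragment_mass, intensity = d$intensity)
}

#' Write / read a de novo peptide table
#'
#' CSV emulating a de novo export: Peptide, ALC (percent), local_confidence
#' (space-separated per-residue percents), Mode, Spectrum, w_ion
#' (space-separated I/L/. per residue).
#'
#' @param peptides a \linkS4class{DeNovoPeptideSet}
#' @param file path
#' @export
writePeptideCSV <- function(peptides, file) {
    d <- data.frame(
        Peptide = peptides@sequence,
        ALC = round(peptides@alc * 100, 1),
        local_confidence = vapply(peptides@confidence, function(x)
            paste(round(x * 100), collapse = " "), character(1)),
        Mode = peptides@mode,
        Spectrum = peptides@spectrumId,
        w_ion = vapply(peptides@wIon, function(w)
            paste(ifelse(w == "", ".", w), collapse = " "), character(1)))
    utils::write.csv(d, file, row.names = FALSE, quote = TRUE)
}

#' @rdname writePeptideCSV
#' @param table a \code{\link{residueTable}}
#' @export
readPeptideCSV <- function(file, table = residueTable()) {
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
    stopifnot(all(c("Peptide", "ALC", "local_confidence") %in% names(d)))
    conf <- lapply(strsplit(d$local_confidence, " +"), function(x)
        as.numeric(x) / 100)
    wIon <- if ("w_ion" %in% names(d))
        lapply(strsplit(d$w_ion, " +"), function(x)
            ifelse(x == ".", "", x)) else NULL
    deNovoPeptideSet(d$Peptide, confidence = conf, alc = d$ALC / 100,
                     mode = if ("Mode" %in% names(d)) d$Mode else NULL,
                     spectrumId = if ("Spectrum" %in% names(d))
                         as.character(d$Spectrum) else NULL,
                     wIon = wIon, table = table)
}

#' Write chain sequences as FASTA
#'
#' @param chains named list of residue token vectors (modification
#'   annotations are written into the header, not the sequence)
#' @param file path
#' @export
writeFastaChains <- function(chains, file) {
    out <- character(0)
    for (nm in names(chains)) {
        toks <- chains[[nm]]
        mods <- grepl("\\(", toks)
        hdr <- paste0(">", nm)
        if (any(mods))
            hdr <- paste0(hdr, " mods=",
                          paste(sprintf("%s@%d", toks[mods], which(mods)),
                                collapse = ","))
        s <- paste(substr(toks, 1, 1), collapse = "")
        out <- c(out, hdr,
                 substring(s, seq(1, nchar(s), 60),
                           pmin(seq(1, nchar(s), 60) + 59, nchar(s))))
    }
    writeLines(out, file)
}

#' Write the antibody-group pairing report
#'
#' Emits a JSON report plus a TSV mirroring the pairing summary (one row
#' per chain of each antibody group: subunit mass, reduced mass with ppm,
#' whole mass with ppm).
#'
#' @param groups output of \code{\link{pairAntibodies}}
#' @param file base path; \code{.json} and \code{.tsv} are appended
#' @export
writeAntibodyReport <- function(groups, file) {
    jsonlite::write_json(groups, paste0(file, ".json"), digits = NA,
                         dataframe = "rows", auto_unbox = TRUE)
    rows <- list()
    for (g in seq_len(nrow(groups))) {
        gr <- groups[g, ]
        rows[[length(rows) + 1L]] <- data.frame(
            group = g, chain = "HC",
            subunit = sprintf("%s+%s", gr$fd, gr$fc2),
            reduced_mass = sprintf("%.2f (%.1f ppm)", gr$hcReduced, gr$hcPpm),
            whole_mass = sprintf("%.2f (%.1f ppm)", gr$wholeObserved,
                                 gr$wholePpm))
        rows[[length(rows) + 1L]] <- data.frame(
            group = g, chain = "LC", subunit = gr$lc,
            reduced_mass = sprintf("%.2f (%.1f ppm)", gr$lcReduced, gr$lcPpm),
            whole_mass = "")
    }
    tb <- if (length(rows)) do.call(rbind, rows) else
        data.frame(group = integer(0))
    utils::write.table(tb, paste0(file, ".tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(tb)
}
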
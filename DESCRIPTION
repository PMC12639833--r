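Package: AbSeqMS
Title: De Novo Polyclonal Antibody Sequencing from Integrated Mass
    Spectrometry Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Assembles antibody subunit sequences (light chain, Fd, Fc/2)
    from bottom-up de novo peptide reads guided by middle-down c/z fragment
    masses, and pairs the assembled subunits into whole antibodies using
    intact proteoform masses, entirely database-free. Provides feature-based
    intact mass deconvolution with targeted inclusion-list generation, an
    isobaric mass-block overlap graph with positional confidence
    accumulation, discretized-mass dynamic-programming assembly scored
    against middle-down prefix and suffix residue masses, homology-based
    isobaric error correction with Ile/Leu resolution from w-ion evidence,
    intact-mass-consistent heavy/light chain pairing, and a synthetic-data
    generator that emulates all three data layers so the whole workflow is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
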
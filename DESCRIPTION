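Package: ap2erf
Title: Identification and Classification of the AP2/ERF Transcription
    Factor Superfamily from Transcriptome Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for the AP2/ERF transcription factor
    superfamily in assembled transcriptome contigs. Translates contigs in
    six frames, locates AP2 and B3 DNA-binding domains with a
    position-specific scoring model, classifies genes into the AP2, ERF,
    RAV and Soloist families from their domain architecture, assigns ERF
    groups by neighbour-joining placement against labelled references
    supported by group-diagnostic residues, discovers per-group diagnostic
    residues and conserved motifs, summarises per-tissue read
    distributions and qPCR relative abundances, and predicts miRNA binding
    sites under a plant-miRNA penalty scheme with a per-pair duplex energy
    model. A synthetic-cohort generator provides labelled ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
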
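Package: sevenTMscreen
Title: Consensus Screening of Transcriptome ORFs for G Protein-Coupled
    Receptor Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen an assembled transcriptome for candidate G
    protein-coupled receptors (GPCRs). Extracts open reading frames from all
    six reading frames of unigene sequences, classifies them by predicted
    transmembrane topology with an explicit length/helix-count/stop-codon
    decision tree, merges evidence from four prediction approaches (alignment,
    topology, and two composition-based classifiers) into consensus candidate
    sets with subfamily-consistency reporting, scores helix integrity of 3D
    model chains, and builds neighbor-joining trees of candidates. Includes
    alignment-free sequence descriptors (amino acid, dipeptide and pseudo
    amino acid composition, autocorrelation, CTD, quasi-sequence-order), a
    deterministic stand-in classifier, parsers for TMHMM, BLAST tabular, Pfam
    and PDB outputs, and a synthetic transcriptome generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
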
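Package: extscan
Title: Identification and Classification of Extensin Proteins in Plant Proteomes
Version: 1.0.0
Authors@R: person("Ohio", "Extensin Lab", email = "extscan@example.org", role = c("aut", "cre"))
Description: Screens predicted plant proteomes for extensins (EXTs), the
    cell-wall hydroxyproline-rich glycoproteins defined by repeated
    Ser-Pro(3-5) motifs. Locates SP_n runs, Tyr-X-Tyr cross-linking motifs
    and AGP-style dipeptides; predicts signal peptides, transmembrane
    segments, GPI omega-sites and composition-biased HRGP domains with
    documented heuristics (with adapters for external predictor output);
    gathers domain-homology evidence via exact Smith-Waterman alignment
    against a bundled reference set; classifies candidates into seven EXT
    classes (classical, short, LRX, PERK, FH, long chimeric, other
    chimeric) or potential EXT; and computes class-level summary
    statistics. Ships a seeded synthetic-proteome generator with planted
    ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
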
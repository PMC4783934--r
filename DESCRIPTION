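Package: milkmiR
Title: Small RNA Profiling and Lipid-Metabolism miRNA Screening for Two-Library Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing toolkit for unreplicated
    two-library comparisons, as used to profile miRNAs in bovine primary
    mammary epithelial cells from high- and low-milk-fat animals. Collapses
    reads to unique tags and annotates them against ncRNA and known miRNA
    references; predicts novel miRNA hairpins from genome-mapped tags with
    the ten Mireap-style Drosha/Dicer duplex constraints; computes normalized
    expression (reads per million, floored), log2 fold changes, exact
    Audic-Claverie two-library p-values, Benjamini-Hochberg FDR and
    significance labels; scores miRNA-3'UTR complementarity with the
    Allen/Schwab position-weighted penalty rules; performs hypergeometric
    pathway enrichment; and screens differentially expressed miRNAs for
    inverse-concordant, pathway-annotated targets. A synthetic-data module
    generates genomes, hairpin loci and two-condition read sets with known
    ground truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
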
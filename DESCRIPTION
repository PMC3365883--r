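Package: barcodediet
Title: COI Barcode Identification of Predator and Prey from Stomach Contents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for DNA-barcode based diet analysis from degraded
    stomach-content amplicons of the mitochondrial COI gene. Provides
    sequence quality control for short fragments (mini-barcodes),
    semi-global alignment of fragments against a reference barcode
    library, Kimura two-parameter (K2P) distances with pairwise deletion,
    a 3 percent divergence rule for species-level assignment,
    neighbor-joining trees with a clade-nesting "strict criterion"
    fallback for queries without close reference matches, and diet
    composition statistics (percent composition by number, taxon
    richness, new regional records, cannibalism detection, and base
    composition summaries). Includes a K80 substitution-model simulator
    that generates taxonomy-structured reference libraries and degraded
    query fragments for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    seqinr,
    phytools,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
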
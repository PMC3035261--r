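Package: gbdp
Title: Genome BLAST Distance Phylogeny Distances and Digital DNA-DNA
    Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes intergenomic distances from sets of high-scoring
    segment pairs (HSPs) or maximal unique matches (MUMs) following the
    Genome BLAST Distance Phylogeny (GBDP) approach: built-in seed-and-extend
    HSP and MUM finders, ingestion of BLAST tabular and MUMmer match files,
    a condensed CGVIZ match format, e-value filtering, greedy-with-trimming
    overlap resolution, coverage-based distances, three distance formulas,
    and conversion of distances into digital DNA-DNA hybridization (DDH)
    percent similarities with species-delimitation calls via a shipped
    registry of calibrated regression constants. Includes a seeded synthetic
    genome-pair simulator and Phylip/Nexus distance-matrix writers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
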
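Package: umiscan
Title: Detection of Ultramicro Inversions Hidden in Pairwise Genome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans local pairwise genome alignments for ultramicro inversions,
    inverted segments of 5-125 bp that are small enough to remain buried inside
    a single local alignment as a cluster of mismatches and gap blocks.
    Implements the trio/duo difference-cluster probability scan, a word-seeded
    inverted-homology search with blastn-like scoring, AT-repeat exclusion
    filters, an HKY+gamma sequence-pair simulator with Lavalette indel lengths
    for sensitivity and false-positive benchmarking, outgroup phylogenetic
    profiling for lineage assignment of inversions, and permutation tests for
    proximity of inversions to genomic features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
SystemRequirements: mafft (optional, for the external realignment engine)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
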
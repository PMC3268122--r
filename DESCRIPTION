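Package: hybridasm
Title: Hybrid Microbial Genome Assembly by Consensus Contig Selection and
    Comparative-Contig Reliability Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles multiple de novo short-read assemblies of the same
    microbial genome with comparative (reference-guided) assemblies built
    against diverged reference genomes. De novo contigs are selected by a
    containment-voting consensus across assemblers, comparative contigs are
    screened for misassembly by best-hit alignment coverage of the consensus
    contigs, and the two sets are merged into a hybrid assembly by greedy
    exact-overlap layout. Includes a maximal-exact-match aligner with colinear
    chaining, assembly quality metrics (genome-relative N50, accuracy against
    a truth genome, repeat complexity, inter-genome similarity), and a seeded
    simulator for genomes with planted repeats, diverged references,
    forward-reverse paired-end reads, and labeled fixture contig sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
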
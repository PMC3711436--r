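Package: mitobaitr
Title: Iterative Baiting and Mapping Assembly of Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs complete circular mitochondrial genomes from
    whole-genome shotgun read pools by iterative in silico baiting and
    mapping: reads sharing exact k-mers with the current reference are
    recruited, placed by tolerant overlap alignment, and collapsed into an
    extended consensus until the recruited read count becomes stationary.
    Starting points can be the mitogenome of a distant relative or a short
    barcode (e.g. COI) seed. Includes a strict paired-end proofreading mode
    for pooled or metagenomic samples, a small greedy de novo assembler for
    verification, a paired-end read and genome simulator, and evaluation
    utilities (assembly comparison, read-recruitment metrics, k-mer spectrum
    genome-size and copy-number estimation, Kimura two-parameter distances).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
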
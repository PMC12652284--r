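Package: tRNAtandem
Title: Conservation Statistics and Tandem-Duplication Detection for tRNA
    Gene Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of nuclear tRNA gene complements across
    species: descriptive conservation statistics (gene-length and
    intron-length distributions, sliding-window GC profiles over
    length-normalised gene positions, species-by-anticodon abundance
    matrices, genome-size correlations) and detection of tandemly
    duplicated tRNA genes (proximal pair finding under an inter-gene
    distance threshold, exact and alignment-based identity
    classification, cluster chaining, and periodic repeat-unit
    decomposition of multi-isotype arrays). Includes a Needleman-Wunsch
    global aligner with affine gaps and free end gaps, a greedy
    identity/coverage sequence clusterer, readers and writers for
    tRNAscan-SE tabular output and FASTA, and a seeded generator of
    synthetic multi-species tRNA annotation fixtures with planted tandem
    arrays for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
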
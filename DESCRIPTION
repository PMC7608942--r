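Package: msynnet
Title: Phylogenomic Microsynteny Network Analysis of Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects pairwise collinear gene blocks between annotated
    genomes by dynamic-programming anchor chaining, assembles a global
    microsynteny network, extracts gene-family subnetworks, finds
    overlapping syntenic communities by k-clique percolation, profiles
    community presence across a species tree, and quantifies divergence
    between syntelog groups with Nei-Gojobori (NG86) Ka/Ks estimates on
    codon alignments.  Ships a genome-evolution simulator (whole-genome
    duplication and triplication with fractionation, tandem duplication,
    DNA- and RNA-mediated transposition, inversion, gene loss, and
    synonymous coding-sequence divergence) that generates complete
    pipeline inputs together with ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'collinearity.R'
    'network.R'
    'communities.R'
    'io.R'
    'molevo.R'
    'msynnet-package.R'
    'profiling.R'
    'simulate.R'
    'pipeline.R'
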
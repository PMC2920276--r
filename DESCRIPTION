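Package: phylofoot
Title: Group-Wise Phylogenetic Footprinting and Motif-Graph Clustering
    for Prokaryotic Regulatory Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: De novo, genome-wide prediction of transcription factor
    binding sites (TFBSs) simultaneously in a group of related
    prokaryotic genomes.  Operons are clustered across genomes through
    bi-directional best-hit orthology into clusters of operons with
    orthologous relationships (COORs); upstream inter-operonic sequences
    of each COOR are mined with an ensemble of motif finders (a built-in
    Gibbs site sampler by default); the resulting candidate motifs are
    filtered through a cascade of motif-similarity graphs clustered with
    Markov clustering (MCL) and quasi-clique detection; and the surviving
    per-genome motifs are ranked by a coverage-weighted information
    content score.  Includes a synthetic genome-group simulator with
    planted motifs and evaluation statistics (site/motif recovery,
    unique-site counts, saturation analysis) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    ape,
    igraph,
    methods,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
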
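Package: metalign
Title: Meta-Alignment by Partitioning of Large Multiple Sequence Alignment Problems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scaling multiple sequence alignment to long and deep
    problems by partitioning them into smaller sub-problems that are solved
    with an existing (pluggable) aligner and reassembled. Length-wise
    partitioning tiles a problem into semi-independent blocks using sparse
    pairwise position constraints and the partial order they induce.
    Depth-wise partitioning decomposes a rooted binary phylogeny into a
    minimum number of sequential stages of bounded-size sub-tree alignment
    problems with inferred root sequences, then merges the sub-alignments.
    Includes a deterministic built-in progressive aligner, a wrapper for
    external command-line aligners, a hierarchical job executor with serial
    and local parallel modes, an alignment agreement scorer, and a neutral
    sequence-evolution simulator (HKY substitutions plus indels) that emits
    leaf sequences together with the true alignment for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    igraph,
    Matrix,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
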
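Package: aftree
Title: Alignment-Free Phylogenetic Inference for Marker-Gene Surveys
Version: 0.1.0
Authors@R:
    person("Yi", "Fan", email = "yifan@example.org", role = c("aut", "cre"))
Description: Alignment-free phylogenetic inference for 16S rRNA-style marker
    gene surveys. Computes pairwise evolutionary distances without multiple
    sequence alignment using three approaches (average common substring
    matching statistics, Markov-corrected k-mer composition vectors, and a
    shortest-unique-substring mismatch estimator with Jukes-Cantor
    correction), builds neighbor-joining trees, combines them into
    majority-rule consensus ensembles with least-squares averaged branch
    lengths, scores trees against taxonomy-derived gold standards
    (Robinson-Foulds and branch-score distances), and provides
    phylogeny-aware community statistics (weighted UniFrac, principal
    coordinates analysis, PERMANOVA with omega-squared effect sizes,
    strata and sequential designs). A simulation module generates Yule
    trees, Jukes-Cantor sequence evolution, tree-consistent taxonomies and
    two-group community abundance tables with a label-permutation effect
    injection, supporting end-to-end method evaluation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
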
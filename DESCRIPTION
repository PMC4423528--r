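Package: essalign
Title: Comparison of Metabolic Pathways via Enzymatic Step Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms KEGG KGML metabolic maps into linear Enzymatic Step
    Sequences (ESS) of three-level Enzyme Commission codes via breadth-first
    search trees, aligns ESS pairwise with a genetic algorithm minimizing an
    entropy-based objective function (weighted per-level Shannon column
    entropy, gap-concentration penalty and column-increment penalty), builds
    all-against-all similarity matrices, estimates alignment significance
    from shuffled sequences, clusters ESS with replicated k-medoids and an
    elbow criterion, and produces progressive multiple alignments of each
    cluster. Includes a synthetic fixture generator (KGML-like maps and ESS
    collections with planted motifs and planted cluster structure), an exact
    brute-force alignment oracle and a Needleman-Wunsch baseline for
    validating the genetic algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    cluster,
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
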
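Package: thermidr
Title: Intrinsic Disorder Abundance Versus Optimal Growth Temperature in
    Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the abundance of intrinsically
    disordered proteins (IDPs) relates to the optimal growth temperature
    (OGT) of bacterial species while controlling for shared ancestry.
    Implements charge-composition metrics (fraction of charged residues,
    net charge per residue) and the five-region diagram-of-states
    classification of disordered sequences; rule-based IDP candidate
    filtering; greedy global-identity ortholog clustering; identity
    distances and UPGMA species trees from aligned 16S sequences;
    least-squares (residual-sum-of-squares minimizing) ancestral state
    reconstruction with quasi-independent sibling contrasts and
    origin-fixed contrast regression; thermophile/mesophile group
    summaries; aligned disorder-score tracks with moving-average
    smoothing; and a synthetic-data generator (Brownian-motion traits,
    Jukes-Cantor 16S-like sequences, composition-templated proteomes)
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
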
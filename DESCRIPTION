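Package: vdjlineage
Title: VDJ Annotation, Clonal Lineage Assembly, and Somatic Hypermutation
    Analysis for B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates B-cell receptor heavy-chain reads against germline
    V, D, and J gene databases using a consecutive-run alignment score with
    mismatch leniency, corrects V-segment indels, locates the CDR3 between
    the conserved 104Cys and 118Trp anchors, clusters clonally related
    sequences with an asymmetric somatic-hypermutation distance, assembles
    rooted multifurcating lineage trees, and refines D-gene and N-region
    calls with a terminal-deoxynucleotidyl-transferase insertion model.
    Includes a truth-annotated repertoire simulator and evaluation metrics
    (gene-match rates, per-position mutation confusion statistics,
    substitution-propensity matrices, hot-spot profiles, gene usage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
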
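Package: glyconet
Title: Rule-Based Construction of N-Glycosylation Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated construction of N-glycan biosynthesis reaction networks
    from enzyme reaction rules. Glycans are modelled as rooted trees of
    monosaccharide residues written in LinearCode; a bundled database of 27
    reaction rules covering 22 Golgi glycosyltransferases and glycosidases is
    applied iteratively (breadth-first, with canonical-form deduplication) to a
    starting glycan such as Man9GlcNAc2, yielding a directed reaction network
    whose nodes are glycan species and whose edges are single enzymatic steps.
    Includes a pattern dialect for substrate specificity (terminal anchors,
    wildcards, branch-context constraints), per-round network summaries, pruning,
    and export to GraphML, SIF, DOT and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    igraph,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
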
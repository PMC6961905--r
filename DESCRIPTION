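Package: ideotree
Title: Parsimony and Treeness Analysis of Cultural Character Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic analysis of cultural data coded as
    multistate character matrices, in particular historical diagrams of the
    tree of life treated as operational taxonomic units. Provides NEXUS
    character-matrix input/output with missing and inapplicable cells, Fitch
    parsimony scoring and seeded heuristic search (random addition plus
    NNI/SPR/TBR branch swapping) rooted on an all-zero hypothetical ancestor,
    strict consensus, ACCTRAN/DELTRAN character optimization with
    gain/reversion/convergence event listings, treeness statistics
    (consistency index, retention index, homoplasy excess ratio with a
    permutation null, quartet delta-score), Bremer decay support via
    reverse-constraint search, date-directed inference of the circulation of
    ideas among homoplastic character states, and a synthetic-data generator
    with controllable vertical and horizontal (borrowing) transmission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
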
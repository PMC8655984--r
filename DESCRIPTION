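Package: rwrscreen
Title: Network Propagation and Screening for Disease-Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by random walk with restart
    over a confidence-weighted protein-protein interaction network seeded
    with validated disease genes, followed by three screening filters: a
    permutation Z-score against random seed sets, a maximum linkage score
    against the validated genes, and a maximum enrichment score comparing
    hypergeometric functional-annotation profiles. Includes readers for
    STRING-style edge lists, gene lists and GMT annotation files, a
    synthetic planted-module benchmark generator, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    optparse,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
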
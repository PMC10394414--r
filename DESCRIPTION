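Package: pksminer
Title: Mining, Deduplication and Comparative Analysis of Assembly-Line
    Polyketide Synthase Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds non-redundant catalogues of assembly-line (modular)
    polyketide synthase (PKS) gene clusters from nucleotide sequence data.
    Detects ketosynthase (KS) domains by six-frame translated local
    alignment against a consensus KS protein, merges hits into discrete KS
    loci, calls candidate multi-modular clusters, classifies their
    cis-AT/trans-AT/hybrid architecture, removes identical and highly
    similar (redundant) clusters using a coverage-weighted local-alignment
    similarity score, and derives catalogue-level statistics: discovery
    time series and doubling time, rediscovery rate, novelty fraction,
    similarity networks and UPGMA dendrograms, and detection of GRINS
    (genetic repeats of intense nucleotide skews). Includes a synthetic
    cluster generator with ground-truth manifests so every stage is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
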
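Package: rnamodcensus
Title: Staged Census and Classification of Epitranscriptomic Marks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ships a curated, machine-readable census of known RNA
    modifications and organizes it as a rooted modification forest: each
    modified ribonucleoside descends from one of the four natural bases
    (A, C, G, U) through successive single chemical-modification steps,
    and its stage is the number of steps separating it from the root.
    Provides a parser for RNA-modification short names (m6A, m2,2G,
    mcm5s2U, ...) that recovers the root base and the multiset of
    chemical operations, validators that keep the census internally
    consistent, per-stage count statistics, annotation queries (kingdom,
    RNA class, tRNA position, mRNA region, motif, enzyme), and
    deterministic DOT, Newick and node-link JSON exporters plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stringi, stats, utils
Suggests: testthat (>= 3.0.0), ape, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
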
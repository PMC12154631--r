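Package: altrin
Title: Residue Interaction Networks from Alternate Conformations in
    Multiconformer Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted residue interaction networks from coupled
    alternate conformations (altlocs) in crystallographic multiconformer
    models such as qFit outputs, aligns the per-structure networks onto a
    common reference through a structure-based multiple sequence
    alignment, log-normalizes and aggregates them into sum networks over
    many related structures, and compares subset networks to map
    conformational-coupling (allosteric) rewiring: weighted-degree
    differences between structure subsets, random-half negative controls,
    Girvan-Newman community detection at the modularity plateau, and
    colocalization statistics of the network against residue sets of
    interest. Includes a synthetic-structure generator with known
    ground-truth networks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
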
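Package: orthoqc
Title: Annotation-Aware Quality Assessment of Orthology Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates how structural genome annotation affects orthology
    inference. Provides intron-chain based agreement statistics between
    gene-model sets annotated on the same assembly, per-proteome ortholog
    proportions and singleton sets, quality metrics for hierarchical
    orthologous groups (counts, sizes, completeness, phyletic patterns),
    a species-tree discordance benchmark scored by scaled Robinson-Foulds
    distances of neighbor-joining gene trees, and protein-length
    diagnostics (medians, Kolmogorov-Smirnov distances, ortholog versus
    singleton splits). A gene-family birth-death simulator with optional
    whole-genome duplication, sequence evolution, toy gene models and an
    annotation-perturbation layer (missing, fragmented and spurious gene
    models) supplies datasets with known ground-truth orthology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
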
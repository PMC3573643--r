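Package: phyloconflict
Title: Diagnosing Phylogenetic Incongruence Between Morphological and
    Molecular Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting phylogenetic conflict between data
    partitions. Quantifies character-state exhaustion in morphological
    matrices (state:step curves, breakpoint regression, rarefaction and
    power-law accumulation models), profiles substitution saturation in
    molecular partitions (transition/transversion slopes against
    model-corrected distances, base-composition homogeneity tests,
    exclusion/down-weighting rules), computes per-character homoplasy
    indices and ACCTRAN change maps on a reference tree, localizes node
    support with partitioned likelihood support and RELL-based weighted
    Shimodaira-Hasegawa and approximately unbiased topology tests, and
    tests adaptive molecular convergence with nearly-neutral versus
    clade-model-C codon models, empirical-Bayes site flagging, and
    per-site amino-acid support profiles under the mtMAM model.
    Includes simulators for partitioned nucleotide, codon, and bounded
    state-pool morphological data so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    minpack.lm,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
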
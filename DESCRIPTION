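Package: latnet
Title: Lateralized Language Network Identification from Task Activation and
    Intrinsic Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies plurimodal word-processing networks from homotopic-pair
    region-of-interest (hROI) analyses of task fMRI and resting-state
    connectivity. Selects regions jointly activated and asymmetric across
    production, listening and reading contrasts via per-task conjunction tests;
    characterizes their task profiles with repeated-measures mixed-effects
    models and Tukey range tests; and partitions them into intrinsic-connectivity
    networks by agglomerative clustering of Fisher-z-averaged correlation
    matrices with multiscale-bootstrap approximately-unbiased (AU) cluster
    support. Includes a synthetic-cohort generator with planted lateralization
    and network structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    lme4,
    lmerTest,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
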
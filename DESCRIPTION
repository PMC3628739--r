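Package: grnbench
Title: Benchmarking Gene Regulatory Network Inference Under
    Environmental Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for studying how environmental
    conditions (no stimulus, constant rich-media stimulus, transient
    spike-in stimulus) affect the performance of mutual-information
    based gene regulatory network inference algorithms. Provides signed
    directed network generators, a stochastic kinetic simulator of
    transcription regulation, empirical, Miller-Madow and Gaussian
    mutual information estimators, from-scratch implementations of
    C3NET, BC3NET, CLR, MRNET and ARACNE, and precision/recall/F-score
    evaluation of inferred networks against the ground truth, organised
    as an ensemble design over observational time points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), optparse, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
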
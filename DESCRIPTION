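Package: pathpid
Title: Path-Based Partial Information Decomposition for Discrete Systems
Version: 0.1.0
Authors@R:
    person("pathpid", "maintainers", email = "pathpid@example.org", role = c("aut", "cre"))
Description: Models pairwise associations between discrete random variables as
    discrete memoryless channels (row-stochastic transition tensors), composes
    them along paths to obtain path-based mutual information, and decomposes
    multivariate information into redundant, unique and synergistic atoms on
    Williams-Beer redundancy lattices via Moebius inversion. Includes
    association-graph inference (absent and cascade-explained edges), the
    classical Imin reference measure, an axiom-verification suite, programmatic
    reconstructions of standard benchmark distributions (Xor, And, PwUnq,
    dyadic/triadic, ...), random channel-system generators for property
    testing, TSV/CSV/JSON serialization of probability tables and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
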
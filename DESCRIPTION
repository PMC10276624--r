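Package: edmorph
Title: Embedded-Dependency Markov Models for Inapplicable Morphological
    Characters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Continuous-time Markov models for anatomically dependent
    (inapplicable) morphological characters. Provides rate-matrix
    amalgamation for character hierarchies (independent SMM amalgamation
    and the embedded-dependency ED-ql and ED-bd amalgamations), the
    dependency-diagram amalgamation (DDA) algorithm for arbitrary
    hierarchies, recoding of multi-column hierarchies into single
    amalgamated characters, rooted-tree pruning likelihoods with
    variable-only (Mkv) conditioning, exact simulators for ED processes,
    and a small Bayesian engine (clock MCMC over rooted time trees,
    stepping-stone marginal likelihoods, consensus and MCC tree
    summaries) able to rerun the accompanying simulation studies at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
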
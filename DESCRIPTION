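Package: weam
Title: Weighted Entropic Associative Memory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A table-based declarative model of associative memory. Objects
    are discrete functions stored by superposition in a single weighted
    register (a columns-by-rows table of non-negative integer weights), with
    a Hebbian-style register operation, a logical recognition test with
    direct cue rejection, and a constructive Bayesian retrieval operation
    that samples each argument from the product of the column weight
    distribution and a discretized normal kernel around the cue. Shannon
    entropy of the columns measures the indeterminacy of the stored content
    and determines the memory capacity. Includes a linear quantizer mapping
    real-valued feature vectors to discrete levels, a synthetic
    Gaussian-cluster corpus generator, scoring conventions for responses
    with a rejection option, and runnable protocols for fill sweeps, noise
    sweeps, association chains and cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
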
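Package: sigstr
Title: Information-Theoretic Quantification of Cell-Signaling Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies signal transduction through phosphorylation cascades
    from phospho-antibody microarray time courses. Normalizes raw array
    intensities to phosphorylation ratios, estimates per-molecule signal
    durations by linear zero-crossing, computes signal transduction rates
    (STR) as the Kullback-Leibler information gain per minute, decides STR
    similarity between cascade steps with a Bayesian two-of-three rule
    (effect size, probability of dominance, direction probability), calls
    cascade activation against a negative-control noise floor, and embeds
    replicate STR vectors in two dimensions for visual clustering. Includes
    a synthetic phospho-array generator with closed-form ground truth and a
    numerical verification of the entropy-maximization theory that predicts
    constant STR along an activated cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
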
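Package: tsstream
Title: Time-Resolved Word Similarity from Message Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a time-resolved semantic similarity between terms from
    any time-stamped message corpus. The similarity of a term pair at a time
    point is the rate of messages containing both terms, normalised by the
    larger of the two individual rates and raised to a scaling exponent;
    rates are estimated from the inter-arrival times of the last N matching
    messages, so the measure can be evaluated inside narrow temporal windows.
    Includes a Poisson topic-mixture stream simulator with analytic ground
    truth, dynamics analyses (concept drift against anchor groups,
    group-organisation performance, matrix-norm reorganisation series),
    evaluation harnesses (synonym ranking, cross-validated classification of
    similarity rows, classical multidimensional scaling), and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    class,
    e1071,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
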
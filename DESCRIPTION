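Package: crisistalk
Title: Computational Discourse Analysis of Crisis Counseling Conversations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale quantitative analysis of two-party crisis
    counseling conversations: a constrained left-to-right conversation-stage
    hidden Markov model trained with expectation maximization, TF-IDF based
    measures of counselor adaptability to conversation trajectory,
    ambiguity and situation-setter analyses with nearest-neighbour response
    clustering, linguistic style coordination (accommodation) statistics,
    psycholinguistic perspective-change trajectories, and prefix-based
    conversation outcome prediction with penalized logistic regression.
    Includes a synthetic conversation-corpus generator with planted,
    recoverable structure so every analysis can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
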
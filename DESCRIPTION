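Package: korders
Title: Extracting Transitive Preference Relations from Paired-Comparison Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clustering of forced-choice paired-comparison response patterns
    into collections of strict linear orders ("preference states"). Implements
    the dichotomous k-modes baseline and the k-orders algorithm, in which the
    modal centroid adjustment is replaced by a transitive centroid adjustment
    (path-finding TCA, or greedy TCA based on incremental acyclic insertion),
    optionally under a monotonicity constraint for two-component option
    designs. Includes a synthetic-data generator (random linear orders, random
    linear extensions of a pointwise order, per-pair response inversion
    probabilities), recovery indexes (true-positive rate, average minimum
    discrepancy), an incremental-extension model-selection procedure with a
    cross-validated max-distance criterion, and a restricted latent class
    model (basic local independence model, BLIM) with EM estimation, AIC/AICc,
    and parametric-bootstrap goodness of fit for empirically validating
    extracted structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
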
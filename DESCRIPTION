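Package: muscleNet
Title: Hub-Anchored Mutual-Information Networks for Multi-Modal Muscle
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative network analysis of skeletal-muscle cohorts that
    combine whole-body physiology, serum protein levels and muscle gene
    expression.  Variables are standardized onto a common scale and
    hub-anchored network modules are inferred with a kernel mutual-
    information estimator whose edge significance is calibrated by a
    permutation null with an exponential tail extrapolation; modules are
    merged into a signed interaction network with optional data-processing-
    inequality pruning.  Companion tools quantify the coupling between
    tissue-remodelling and bioenergetics sub-networks against a degree-
    preserving permutation null, map differential-expression results onto
    the network, score direction-consistency of a hub neighbourhood against
    external contrasts, test differential expression (paired t-tests with
    Benjamini-Hochberg correction, two-factor ANOVA, fold-change filters,
    hypergeometric gene-set enrichment) and classify samples from small
    gene panels with cross-validated k-nearest neighbours.  A synthetic
    cohort generator with planted module structure, tunable inter-module
    coupling and group-specific training effects provides ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
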
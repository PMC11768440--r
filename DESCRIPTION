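Package: dustrisk
Title: Health-Risk Scoring and Multivariate Structure of Heavy Metals in Urban Dust
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-carcinogenic health-risk assessment of heavy-metal concentrations in
    urban dust (average daily dose by ingestion, inhalation and dermal contact; hazard
    quotients and hazard index), together with the multivariate toolkit used to profile
    the same concentration matrices: principal component analysis with four
    component-selection rules, maximum-likelihood factor analysis with oblimin rotation
    and a full retention battery (parallel analysis, very simple structure, information
    criteria), a from-scratch t-SNE with per-point perplexity calibration, Bayesian
    optimization of the embedding hyperparameters under three quality objectives, cluster
    quality metrics (intra/inter-cluster distance, silhouette, Sammon error), and a
    synthetic concentration-matrix generator with planted latent factors and site
    clusters so the whole pipeline is testable without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
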
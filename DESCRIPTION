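Package: md3f
Title: Distance-Based Drift-Diffusion Modelling of Longitudinal High-Dimensional Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and tests the magnitude of directed drift in longitudinal
    multivariate profiles (microbiome and other omics data) using only interpoint
    distance summaries. Models repeated measures per subject as a drift-diffusion
    stochastic process and fits ordinary least-squares regressions of (time-scaled)
    squared interpoint distances on the time interval; the slope estimates the
    squared drift magnitude and its coefficient t-test provides an omnibus test for
    directed change. Includes compositional (centered log-ratio) transforms,
    Euclidean, Aitchison and Bray-Curtis dissimilarities, principal coordinate
    embedding, univariate and ordination-based baseline tests, a seedable pre/post
    and trajectory simulator, and a simulation-study runner measuring type I error,
    power and estimator bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    sandwich
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
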
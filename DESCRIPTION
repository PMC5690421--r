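Package: neuroforage
Title: Evolution of Neuromodulated Spatial Neural Networks on a Seasonal
    Foraging Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of small, spatially embedded feed-forward
    neural networks that learn a two-season foraging task within their
    lifetime via neuromodulated Hebbian plasticity.  Two modulation schemes
    are provided: standard neuromodulation through dedicated modulatory
    nodes, and diffusion-based neuromodulation in which located point
    sources release a simulated chemical whose concentration falls off as a
    Gaussian with distance.  Networks are evolved with a probabilistic
    multi-objective algorithm (PNSGA) combining task performance,
    behavioral diversity and an optional connection cost.  The package also
    implements the Activation Record Knockout (ARK) procedure that prunes a
    trained network down to its core functional network and labels
    season-specific functional modules, together with seasonal-retention
    metrics for quantifying catastrophic forgetting and Newman modularity
    (Q-score) of the extracted networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
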
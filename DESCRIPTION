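Package: v2pigtm
Title: Generative Topographic Mapping with Visual-to-Parametric Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits Generative Topographic Mapping (GTM) models, a constrained
    Gaussian-mixture latent variable method for visualizing high-dimensional
    data on a two-dimensional lattice, and extends them with
    visual-to-parametric interaction (V2PI): repositioning one plotted
    observation adds a latent anchor and attractor basis function, locally
    rescales the likelihood around the moved observation, refits the model
    conditionally, and blends the pre- and post-interaction manifolds so the
    change stays local. Includes manifold magnification factors, a
    Gini-style term-importance index (ImpI) for featurizing document
    collections, latent-space tagging and k-means cluster keyword
    extraction for text exploration, synthetic data generators, and a
    command-line interface for reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
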
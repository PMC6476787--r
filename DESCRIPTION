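Package: tundradiv
Title: Altitudinal Diversity Gradients and Metacommunity Structure in
    Hierarchical Vegetation Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing vascular-plant diversity along altitude
    gradients in hierarchically structured surveys (mountains, transects,
    stations, one-square-metre plots). Provides alpha diversity (vegetation
    cover, species richness, scaled Shannon evenness from point-intercept
    counts), multi-scale beta diversity as distances to group centroids in
    principal-coordinate space derived from binary Bray-Curtis
    dissimilarities, nestedness (NODF) and bipartite modularity (Barber's Q
    via the BRIM algorithm) under optimal and altitude-imposed matrix
    orderings, a species-frequency-preserving null model with Z-score
    inference, mixed-effects models contrasting linear and quadratic altitude
    trends with nested random effects, and a synthetic survey generator with
    Gaussian altitude niches so every stage can be exercised without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vegan,
    lme4,
    mvtnorm,
    png
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    mclust,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
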
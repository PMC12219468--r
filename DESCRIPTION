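Package: unidim
Title: Universality and Brain Similarity of Network Representational Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies, for every latent dimension (principal component) of a
    neural network layer, how predictable it is from the activations of other
    networks (universality) and from brain responses (brain similarity), using
    nested cross-validated ridge regression, and runs the downstream inference:
    Spearman and partial Spearman correlations, image-label permutation tests,
    quantile summaries, and representational similarity analysis with
    universal-subspace reduction. Includes a synthetic latent-factor world
    generator that emulates the statistical structure of multi-network,
    multi-subject studies, with an aligned regime (brain shares network
    latents) and a null regime (it does not).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
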
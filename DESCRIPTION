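Package: fmcnet
Title: Functional Microbial Community Networks from Compositional Abundance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers microbial co-occurrence networks from genus-level 16S
    abundance tables and dissects them into functional microbial communities
    (FMCs). Pairwise associations are estimated with a sparse compositional
    correlation estimator (SparCC-style log-ratio variance inference with
    Dirichlet resampling of zeros), transformed into a signed weighted
    network by soft thresholding, and clustered on the topological overlap
    measure with a dynamic tree cut. Modules are summarised by their
    eigengenus, related to clinical traits, screened for intramodular hubs,
    and tested for cross-dataset reproducibility with a permutation
    Z-summary preservation statistic. A nearest shrunken centroids
    classifier with leave-one-out cross-validation turns genus-region or
    module-region features into disease-state predictions. A synthetic
    compositional count generator with planted module structure makes the
    whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
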
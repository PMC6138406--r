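Package: elmcc
Title: Molecular Subtyping of Tumors by Random-Projection Dimension
    Reduction of Expression Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised molecular subtyping of tumor cohorts from gene
    expression matrices. A single-hidden-layer feedforward network with
    random, fixed input weights (an extreme learning machine) projects
    high-dimensional expression profiles onto a low-dimensional hidden
    feature space, which is then partitioned by k-means. The package also
    provides the surrounding machinery of a subtyping study: expression
    matrix input/output and MAD-based variance filtering, model selection
    by the gap statistic and by consensus-clustering CDF areas, a
    Monti-style consensus clustering baseline, PCA embedding, cluster
    significance testing (SigClust), silhouette widths, adjusted Rand
    index and hypergeometric concordance, Kaplan-Meier / log-rank survival
    association, cross-cohort classification with a hard-limit ELM
    classifier, and a synthetic cohort generator with known subtype
    structure and subtype-linked survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    survival,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
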
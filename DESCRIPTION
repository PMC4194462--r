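Package: gcnforge
Title: Construction and Multivariate Comparison of Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds gene co-expression networks (GCNs) from preprocessed
    expression matrices and compares many networks at once. Pairwise gene
    similarity is measured with the absolute Pearson correlation (APCC), a
    non-linear correlation coefficient based on mutual information (NCMI),
    or the normalized mean residue similarity (NMRS). A hard similarity
    threshold is selected objectively by contrasting the observed clustering
    coefficient of the thresholded network against its expectation under a
    degree-matched random graph, taking the first local maximum of the
    absolute difference over a fixed threshold grid. Networks are
    characterized by eight graph variables (clustering coefficient,
    centralization, heterogeneity, density, GO and PFAM assortativity,
    attack tolerance and degree-immunity correlation) and compared via
    principal component analysis and K-means clustering with BIC-based
    model selection. Includes seeded generators for power-law networks,
    similarity matrices with a known true threshold, and expression
    matrices with planted linear, inverted, quadratic and shifted
    co-expression, used to validate threshold recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
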
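Package: dcornet
Title: Differential Spearman Correlation Networks for Stratified Tumour Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs condition-specific gene co-expression networks from
    tumour expression cohorts and compares them. Samples are stratified into
    immune-signature high/low groups by Ward clustering, Spearman correlation
    matrices are computed over user-supplied gene panels, networks are built by
    absolute-correlation thresholding with an automatic highest
    non-fragmenting threshold, and the two condition networks are compared via
    global topology metrics (density, centralization, heterogeneity, diameter,
    radius, clustering coefficient), Brandes node and edge betweenness
    rankings, and a DyNet-style per-node rewiring score on the merged network.
    Includes a block-correlated Gaussian-copula cohort simulator with known
    planted rewiring for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
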
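Package: nitromix
Title: Nitrate Source Apportionment and Connectivity-Microbiome Coupling for River-Lake Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain of a river-lake nitrogen study:
    a hierarchical Bayesian dual-isotope (d15N/d18O of nitrate) mixing model
    fitted by adaptive MCMC for source apportionment, aggregation of source
    posteriors into non-point and point-source categories, community diversity
    statistics (Chao1, Shannon, Simpson, Bray-Curtis, PCoA, Mantel, ANOSIM),
    and a connectivity-nitrogen-microbiome coupling analysis via correlation
    suites and piecewise structural-equation path models. A synthetic-data
    module generates isotope mixtures, watershed covariate tables, community
    count tables and paired distance structures with prescribed statistical
    structure, so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
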
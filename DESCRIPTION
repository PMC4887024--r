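Package: pifomics
Title: Spectral-Count Proteomics Differential Expression with Phenotypic
    Impact Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Label-free shotgun-proteomics differential expression from
    spectral counts for a two-group design: total-count normalization, MA
    (log-ratio / average-abundance) construction, empirical-Bayes moderated
    t-statistics with in-package variance-prior estimation, abundance-weighted
    Phenotypic Impact Factor (PIF) ranking with extreme-tail selection,
    exact binomial tests for directional skew of an annotated compartment
    proteome (e.g. the mitoproteome), row-standardized two-way hierarchical
    clustering of top-ranked proteins, two-list hypergeometric enrichment
    with Benjamini-Hochberg correction, and upstream-regulator activation
    z-scores with Fisher overlap tests. Includes a negative-binomial
    synthetic spectral-count generator with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
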
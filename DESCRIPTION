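Package: codeharmony
Title: Detecting and Harmonizing Medical-Code Usage Heterogeneity Across
    Healthcare Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical tools to detect and mitigate differences in how two
    healthcare systems use medical codes, working entirely from data that can
    be exchanged as summary-level aggregates. Provides smoothed person-time
    adjusted frequency ratios, covariate-adjusted weighted t-tests for single
    codes, and burden and SKAT score tests for code groups, together with
    federated versions that reproduce the pooled individual-level results
    exactly from per-site cross-products. Implements embedding-based code
    mapping: pointwise-mutual-information code embeddings from within-patient
    temporal co-occurrence, orthogonal (Procrustes) or ridge-projection
    alignment of the two embedding spaces, cosine and regression similarity
    with optional frequency refinement, top-K or cross-validated threshold
    mapping selection, and a row-stochastic harmonization operator. Includes a
    domain-confusion validation (site-classifier AUC) and a synthetic two-site
    EHR generator with planted coding differences and ground-truth mappings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    stats,
    utils,
    tools,
    sandwich,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
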
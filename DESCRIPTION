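Package: dermclaims
Title: Matched-Cohort Claims Analysis and Short-Term Cost-Effectiveness of
    AI-Based Skin Cancer Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for evaluating the impact of an
    AI-based skin cancer triage app on dermatological healthcare
    consumption using insurer claims data.  Provides a synthetic-cohort
    generator emulating the statistical structure of app-usage and claims
    data, tiered 1:3 exact matching of app users to non-user controls,
    person-level contingency analyses of claims by diagnosis category
    (odds ratios, Fisher exact tests, two-proportion z-tests,
    Benjamini-Hochberg adjustment), per-person and per-claim cost
    comparisons, and a short-term cost-effectiveness model producing the
    incremental cost-effectiveness ratio (ICER) per additionally detected
    (pre)malignancy together with its sensitivity-by-specificity surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
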
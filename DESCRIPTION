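Package: retrievalqc
Title: Quality Assessment of Keyword Search Filters for Social Media
    Health Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to build, apply, and statistically validate boolean
    keyword search filters used to collect social-media messages for
    public-health surveillance (infoveillance). Estimates retrieval
    precision, recall, specificity, and negative predictive value from
    stratified coded samples under four evidence regimes: an error-free
    human gold standard; archives where unretrieved messages were never
    stored (a Gibbs sampler over the latent false-negative count); human
    coding as a silver standard with imperfect recall; and two imperfect
    classifiers with no gold standard (a latent-class Gibbs sampler).
    Includes beta prior elicitation from published means and intervals,
    highest posterior density intervals, stratified sampling-design
    simulation for coding budgets, a boolean keyword filter engine with
    per-keyword screening statistics, a synthetic corpus generator with
    known ground truth for end-to-end validation, and reproducible
    assessment reports following a reporting checklist.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
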
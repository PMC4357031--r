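Package: cpindex
Title: Community Priority Index for Multicriteria Priority Setting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Community Priority Index (CPI), a multicriteria
    priority-setting statistic for panels of stakeholders who rate community
    issues on k-point Likert scales against several decision criteria
    (typically importance and changeability). Provides criterion means under
    missing responses, the product-form CPI, percentile-bootstrap 95%
    confidence intervals with an exhaustive-enumeration oracle for small
    panels, bounds-based standardization onto [0, 1], priority
    classification with configurable cut-offs, population-stratified ranked
    reports, a synthetic rating-panel generator with known truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
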
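Package: biomoe
Title: Margin-of-Exposure Risk Assessment from Urinary Biomarker Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates human biomonitoring and food monitoring data for
    retrospective pesticide risk assessment, with chlorpyrifos and its urinary
    metabolite 3,5,6-trichloro-2-pyridinol (TCPy) as the packaged case study.
    Derives biomonitoring-equivalent points of departure (HBM-PoD) from animal
    points of departure by reverse dosimetry, predicts urinary TCPy
    concentrations from dietary exposure reported as percent of the acceptable
    daily intake, computes margins of exposure against biomonitoring
    percentiles, classifies results with a four-colour uncertainty-factor
    threshold scheme, propagates toxicokinetic parameter ranges into
    margin-of-exposure intervals, and simulates lognormal biomarker populations
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
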
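Package: silicarisk
Title: Task-Based Respirable Crystalline Silica Exposure Modelling and
    Exposure Control Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates respirable crystalline silica (RCS) exposure
    measurements through quality-control rules (standard analytical
    methods, polymorph consolidation, half-LOD substitution for
    non-detects), de-aggregates published summary statistics into
    simulated discrete observations, fits a multiplicative (log-linear)
    determinants-of-exposure model over common silica processes and
    engineering controls, produces Monte Carlo upper 95th-percentile
    exposure estimates for uncontrolled and controlled task scenarios
    with separation-from-source and short-duration adjustment factors,
    compares estimates to an occupational exposure limit with respirator
    recommendations, and assembles regulator-style exposure control plan
    documents with a version-stamped archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
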
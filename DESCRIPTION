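Package: netdea
Title: Network Slack-Based Data Envelopment Analysis with Weakly
    Disposable Undesirable Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Benchmarks decision-making units (hospitals and similar
    service providers) with a network slack-based measure of efficiency
    in which each unit is decomposed into linked divisions and
    undesirable outputs (adverse events, delays) are weakly disposable:
    desirable and undesirable outputs can only be abated jointly through
    a per-peer abatement factor, linearised by splitting the intensity
    vector.  Provides per-division and overall efficiency scores under
    variable or constant returns to scale, scale efficiency, Pearson
    correlation screening and merging of collinear variables, sensitivity
    analysis over correlated-variable substitutions, best-/worst-case
    counterfactual scenario analysis of quality and access variables, and
    a synthetic hospital-panel generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
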
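Package: camobreak
Title: Camouflage-Breaking Analysis with Simulated Dichromat Vision
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies animal camouflage from photographs and models how
    colour vision affects camouflage breaking in visual-search tasks.
    Provides simulated-dichromat image rendering, luminance-channel
    camouflage metrics (granularity pattern difference, luminance
    distribution difference, patch contrast) measured in target, annulus
    and whole-background regions, a generator for synthetic camouflage
    scenes and simulated search-game sessions with censored lognormal
    capture times, event filtering rules, and BIC-based simplification of
    linear mixed models of log capture time, including a parameter
    recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
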
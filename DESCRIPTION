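Package: clockaudit
Title: Auditing Linear DNA-Methylation Age Clocks
Version: 0.1.0
Authors@R:
    person("clockaudit", "developers", email = "clockaudit@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing sparse linear DNA-methylation (DNAm) age
    clocks. Quantifies coefficient-sign incoherence of clock features
    against their univariate age correlation, measures clock dependence on
    leukocyte composition via reference-based deconvolution and variance
    inflation factor (VIF) changes, contrasts elastic-net and ordinary
    least-squares behaviour under CpG multicollinearity, and computes
    variability-based aging metrics (windowed SD/CV "noise barometer" with
    piecewise noise-trajectory fitting). Ships a seeded synthetic beta-value
    cohort generator emulating blood DNAm cohorts, so every analysis stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
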
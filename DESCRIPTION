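Package: pahrisk
Title: Dietary Health Risk Assessment of Polycyclic Aromatic Hydrocarbons in Bread
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toxic-equivalency (TEQ) scoring, dietary exposure and incremental
    lifetime cancer risk (ILCR) estimation for 16 priority polycyclic aromatic
    hydrocarbons (PAHs) measured in staple breads, with left-censored
    (below-detection-limit) concentration handling, seeded Monte Carlo
    uncertainty propagation, contribution-to-variance sensitivity analysis,
    and a synthetic factorial-study generator for end-to-end testing of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
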
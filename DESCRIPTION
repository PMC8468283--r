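Package: grainCOI
Title: Cost-of-Illness Modelling of Whole-Grain Intake and Cancer Healthcare Costs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic cost-of-illness framework linking dietary
    whole-grain intake to direct healthcare expenditure savings. Pooled
    dose-response relative risks are scaled linearly to an intake gap,
    the resulting percent risk reductions (with 95% confidence intervals)
    are applied one-for-one to disease expenditure categories under
    population-uptake scenarios, and annual savings are discounted to
    present value over a staged multi-year adoption timeline. Ships the
    Australian colorectal-cancer and total-cancer input tables as
    plain-text fixtures, a synthetic-input generator for property
    testing, and report writers in CSV, markdown and plain text.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
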
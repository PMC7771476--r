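Package: agsurplus
Title: Ex-Ante Economic Surplus Analysis of Crop Research Options under
    Foresight Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A stylized recursive-dynamic, multi-region, multi-commodity
    partial-equilibrium simulator for ex-ante assessment of agricultural
    research investments. Technology options are specified by research and
    adoption lags, logistic adoption ceilings, expected yield and input-cost
    changes, and probabilities of success; their productivity effects enter
    the market model as shifts of the exogenous yield trend. Welfare impacts
    (producer and consumer surplus on the focus-crop market) are measured
    against scenario baselines, discounted into net present values, and
    summarised with IRR and MIRR for ranking research options under static
    and SSP-RCP-style foresight scenarios, for target countries only or
    globally. Includes a seeded synthetic-data generator so that the whole
    pipeline is testable without proprietary model calibrations, and a
    closed-form economic-surplus oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
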
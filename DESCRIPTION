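Package: crcscreen
Title: Cost-Effectiveness Microsimulation of Colorectal Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov microsimulation of colorectal cancer
    natural history (adenoma-carcinoma sequence) with overlays for fecal
    immunochemical test (FIT) and total colonoscopy (TCS) screening
    strategies under configurable uptake rates. Computes discounted
    lifetime costs and quality-adjusted life-years, colorectal cancer
    incidence and mortality, incremental cost-effectiveness ratios with
    dominance classification, scenario analyses, and probabilistic
    sensitivity analysis with beta/gamma parameter uncertainty. Includes
    a deterministic expected-value cohort engine used as a variance-free
    cross-check of the microsimulation, a parameter-file loader with a
    documented schema, and a synthetic parameter generator so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
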
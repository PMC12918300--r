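Package: gpturnover
Title: Practice-Level Physician Turnover from Consultation Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Measures general-practitioner turnover at primary care practices
    from administrative consultation records. Consultation events are segmented
    into physician-practice spells using a 365-day gap rule, monthly regular
    workforces are defined by a distinct-consultation-day threshold, and
    turnover rates are computed at monthly, annual and practice level over
    horizons of 6 to 60 months, including a supplementary January-workforce
    rate for permanently employed physicians and a permanent/temporary mixture
    decomposition. Practice covariates (size, case-mix, deprivation, ownership,
    location, workload) are tercile-coded and related to turnover through
    bivariate summaries and least-squares regressions with
    heteroskedasticity-robust standard errors. A synthetic care-registry
    generator with known exit hazards supports testing and method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    jsonlite,
    lubridate,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
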
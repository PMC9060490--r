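Package: vaxpanel
Title: Dynamics of Vaccination Attitudes in Longitudinal Survey Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-wave panel surveys of attitudes
    toward voluntary and mandated vaccination measured on a five-point
    Likert scale. Classifies respondents by consistency of opposition or
    willingness across waves, tabulates adjacent-wave attitude switching,
    estimates Markov transition matrices and their stationary (long-run
    equilibrium) distributions, fits a random-misreport measurement-error
    mixture model that bounds the share of hard-core opposition, quantifies
    attitude crowding-out under a hypothetical mandate, and fits logistic
    and linear-probability models of opposition with Tjur's coefficient of
    discrimination for model comparison. A synthetic-panel generator with
    covariate-dependent Markov transitions, misreport contamination and
    end-of-panel vaccination uptake supports simulation studies and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
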
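Package: dfemdt
Title: PBPK Monte Carlo Estimation of 1,1-Difluoroethane Detection Times in Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) modelling of
    1,1-difluoroethane (DFE, HFC-152a) inhalation abuse ("huffing"), with
    Monte Carlo simulation of population variability in body mass index and
    inhalation pattern. Provides a five-compartment perfusion-limited PBPK
    model with an exact closed-form propagator and a fixed-step Runge-Kutta
    solver, square-wave exposure scenario construction, truncated-normal BMI
    population sampling, maximum-detection-time (MDT) estimation against
    blood detection limits, percentile concentration curves, and local
    normalized sensitivity analysis. All results are tibbles designed for
    pipe-based workflows, with broom-style tidiers and ggplot2 autoplot
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
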
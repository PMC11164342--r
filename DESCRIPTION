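Package: ca125dyn
Title: Treatment-Response Dynamics of CA-125 in High-Grade Serous Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models longitudinal serum CA-125 kinetics in high-grade serous
    ovarian cancer under multi-line chemotherapy. Provides per-line estimation
    of data-based resistance and aggressiveness (log-scale slopes on and off
    treatment), exact piecewise propagation and constrained least-squares
    fitting of a two-compartment treatment-sensitive/treatment-resistant ODE
    model and of an adaptive-dynamics model in which a continuous resistance
    level climbs the fitness gradient, model comparison against a
    variable-span smoother (RSS ratio, AIC, in- and out-of-sample R-squared),
    survival stratification of inferred traits (median-split Kaplan-Meier,
    multivariate Cox), and a synthetic cohort generator emulating realistic
    treatment schedules, multiplicative measurement noise and parameter-linked
    survival.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
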
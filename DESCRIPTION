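Package: bpgrowth
Title: Bertalanffy-Puetter Growth Curve Fitting, Model Landscapes and
    Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the two-exponent Bertalanffy-Puetter family of growth
    models dv/dt = p*v^a - q*v^b to longitudinal size-at-age data (e.g.
    tumor volume in mm^3 over days). For every exponent pair (a, b) on a
    grid the three free parameters (p, q, v0) are estimated by least
    squares using a multiplicative simulated-annealing scheme with
    restarts and adaptive cooling, followed by a Levenberg-Marquardt
    polish in log-parameter space. The resulting SSE landscape over the
    exponent grid yields the best fitting model and regions of
    near-optimal models, which quantify model-selection uncertainty.
    Additional tools fit initial data segments and extrapolate them to
    assess the feasible prognosis horizon, compute asymptotic and
    inflection volumes and relative growth rates, test residual
    normality, interpolate data by cubic splines, and construct single
    prediction bands. Ships a 14-point tumor size-at-age fixture used
    throughout the documentation and a seeded synthetic-data generator
    for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    nortest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
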
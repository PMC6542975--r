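Package: eisdry
Title: Equivalent-Circuit Impedance Modelling and Moisture Estimation for Drying Plant Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electrical impedance spectroscopy (EIS) of drying plant
    tissue. Provides impedance-spectrum data structures with polar/cartesian
    conversions and CSV input/output, a series/parallel circuit-expression
    language with resistor, capacitor and constant-phase elements, the classical
    plant-tissue equivalent circuits (Hayden, simplified Hayden, CPE-modified,
    double-shell) plus a two-relaxation series model, complex nonlinear
    least-squares fitting by Nelder-Mead simplex with percentage-error
    goodness-of-fit metrics and model comparison, dry-basis moisture content
    from sample weights, polynomial calibrations of moisture against impedance
    with SSE, R-squared and RMSE, and a synthetic drying-experiment simulator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
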
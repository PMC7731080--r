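Package: bloodEIS
Title: Effective-Medium Modelling of Whole-Blood Impedance Spectra for
    Glucose Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward model and fitting tools for whole-blood electrical
    impedance spectra as a function of glucose concentration. Implements
    the Bruggeman asymmetric effective-medium conductivity of a two-phase
    suspension (insulating red cells and glucose in conductive plasma),
    a cylindrical-vessel impedance model with Debye dielectric relaxation,
    the equivalent five-coefficient rational magnitude form with
    gauge-fixed nonlinear least-squares estimation, percent-error
    reporting against published reference spectra, synthetic spectrum
    generation (including glucose sweeps), CSV spectrum I/O and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
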
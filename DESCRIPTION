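Package: tg51mc
Title: Monte Carlo Uncertainty Propagation for TG-51 Reference Dosimetry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the full TG-51 absorbed-dose-to-water calibration chain
    for megavoltage photon and electron beams and propagates measurement
    uncertainties by Monte Carlo. Provides declarative uncertainty budgets for
    the standard clinical sources (SSD, depth, temperature, pressure, field
    size, beam-quality specifiers, chamber and electrometer calibration,
    recombination and polarity corrections, humidity), per-source labelled
    random streams, sensitivity sweeps, contribution decomposition against the
    Gaussian quadrature oracle, audit out-of-tolerance probabilities, and
    normality diagnostics of the simulated dose distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
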
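Package: spinflex
Title: NMR Spin Relaxation, Chemical Shift Perturbation, and CPMG
    Relaxation Dispersion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A per-residue pipeline for quantitative solution-NMR dynamics
    analysis of membrane proteins and other systems: exponential fitting of
    R1 and R1rho relaxation decays with Monte Carlo error estimation, offset
    correction of R1rho to R2, heteronuclear NOE ratios with propagated
    errors, chemical shift perturbation (CSP) mapping between two ionic
    conditions with a trimmed-mean significance threshold, multi-state peak
    population quantification by 2D Lorentzian lineshape deconvolution, and
    two-state CPMG relaxation dispersion analysis for 13C multiple-quantum
    and 1H single-quantum coherences with global exchange-rate fitting.
    Includes a synthetic-data generator emulating each experiment so the
    whole pipeline is testable without spectrometer data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
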
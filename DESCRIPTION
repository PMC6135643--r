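Package: dmxan
Title: Ensemble-Averaged XANES Fitting and Force-Field Refinement for
    Metal Coordination Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dynamic XANES analysis of metal coordination sites:
    configurational averaging of per-snapshot theoretical absorption
    spectra over molecular-dynamics-style ensembles, quantitative
    comparison to experimental spectra through the square-residual
    statistic R_sq with energy-dependent Lorentzian inelastic-loss
    broadening, convergence diagnostics (R_f), time-windowed fit-error
    series, radial distribution functions with running coordination
    numbers, a Metropolis Monte Carlo sampler of harmonic bonded models
    of the heme-CO site, and a greedy coordinate-descent refinement of
    bonded force-field parameters driven by the spectral residual.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
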
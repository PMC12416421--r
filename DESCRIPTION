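Package: crplasma
Title: Non-Thermal Collisional-Radiative Plasma Modelling of Femtosecond
    X-Ray Damage in Biomolecular Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Zero-dimensional collisional-radiative solver for the electronic
    radiation damage suffered by biomolecular targets under femtosecond X-ray
    free-electron laser pulses. Couples per-element ionic configuration
    populations to a non-Maxwellian free-electron energy distribution
    represented on an adaptive B-spline basis. Atomic data (binding energies,
    photoionization cross-sections, Auger and fluorescence rates,
    binary-encounter-Bethe impact-ionization cross-sections and their
    microreversible three-body recombination kernels) are generated internally
    from a configuration-average self-consistent mean field. Includes cascade
    partitioning of the free-electron density by seeding process, tracer
    electron injection, pulse-parameter scans, and the observables used in
    serial femtosecond crystallography damage studies (average and
    intensity-averaged charges, electron density ratios, ionization contrast).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
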
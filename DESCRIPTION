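Package: edlshyd
Title: Hydration Dynamics from Broad-Band Depolarized Light Scattering Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse extended frequency-range depolarized light
    scattering (EDLS) susceptibility spectra of aqueous peptide solutions.
    Provides closed-form relaxation and oscillator lineshapes (Debye,
    Cole-Davidson, damped harmonic oscillator), spectral reduction from raw
    intensity via the Bose-Einstein occupation factor, segment joining,
    librational-band normalization and solvent-free subtraction, constrained
    multi-component least-squares fitting of pure-water, solvent-free and
    full solution spectra, extraction of hydration numbers and retardation
    factors from fitted relaxation amplitudes, Stokes-Einstein-Debye
    analysis of solute rotation, a geometric Monte-Carlo model of random
    hydration-shell overlap, and a seeded generator of realistic synthetic
    spectra with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
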
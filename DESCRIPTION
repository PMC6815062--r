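Package: boneatten
Title: Ultrasonic Attenuation in Cancellous Bone from Cylinder Scattering and Marrow Absorption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the ultrasonic attenuation coefficient of cancellous
    (trabecular) bone by modelling it as a two-phase composite: a fluid marrow
    matrix with empirical power-law absorption, plus identical solid elastic
    cylinders (trabeculae) whose scattering cross-section is computed from the
    classical phase-shift series for a plane wave incident on an elastic
    cylinder in a fluid. Provides the full partial-wave solution (phase
    shifts, cross-sections, angular scattering patterns, Rayleigh limit),
    composite attenuation spectra in dB/cm, and spectral summaries used in
    bone quantitative ultrasound: broadband ultrasound attenuation (BUA)
    slope, power-law exponent of the scattering component, the
    absorption/scattering crossover frequency, and porosity and
    trabecular-size sweeps. Includes a command-line interface and
    figure-regeneration helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
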
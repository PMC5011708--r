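Package: qenscell
Title: Four-Component Quasi-Elastic Neutron Scattering Analysis of Live Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and fit quasi-elastic neutron scattering (QENS)
    spectra of live cells with a four-component structure factor: an elastic
    fraction, bulk water (jump diffusion convolved with free rotational
    diffusion), hydration water, and a broad Q-independent proteome Lorentzian,
    all convolved with the instrument resolution (analytic Voigt profiles for a
    Gaussian resolution). Provides per-Q model-free Lorentzian fits,
    dispersion-curve (HWHM versus Q squared) extraction with jump-diffusion
    fitting, a global multi-Q weighted least-squares fit with multi-start and
    curvature-based standard errors, a synthetic spectrum generator emulating a
    cold-neutron time-of-flight configuration with Poisson counting noise, and
    an end-to-end simulate/fit/compare pipeline with tidy outputs, broom-style
    tidiers and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
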
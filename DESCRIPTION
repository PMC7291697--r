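Package: drsfit
Title: Diffuse Reflectance Spectroscopy Modelling and Cortical Breach Detection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward and inverse modelling of two-fiber diffuse reflectance
    spectra (450-1600 nm) for optical guidance of pedicle-screw placement.
    Provides a diffusion-approximation forward model of tissue reflectance at a
    fixed fiber separation, bounded nonlinear least-squares recovery of
    oxy-/deoxy-hemoglobin, fat and water content plus power-law reduced
    scattering, delta-method confidence intervals for derived physiological
    parameters (blood content, fat fraction), a synthetic-experiment generator
    emulating probe insertions across vertebral tissue zones, probe-handling
    conditions and post-sacrifice perfusion decay, a fat-fraction-based
    cortical-breach detection pipeline, and the accompanying nonparametric
    statistical toolbox (Jarque-Bera, Wilcoxon rank-sum with exact enumeration).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
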
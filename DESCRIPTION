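Package: layercal
Title: Laminar Multi-Contrast Calibrated fMRI: CBF, CBV, BOLD and CMRO2 Across Cortical Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of laminar multi-contrast functional MRI
    combining arterial spin labeling (ASL) perfusion, vascular space occupancy
    (VASO) blood-volume imaging and T2-weighted BOLD. Implements one-compartment
    pCASL cerebral blood flow quantification, BOLD-corrected VASO cerebral blood
    volume conversion, joint five-unknown breath-hold calibration of the Davis
    model (M, beta and three baselines), Davis-model inversion for laminar CMRO2,
    Grubb power-law coupling estimation, SVD-based slice deblurring, a bootstrap
    two-peak statistic for cortical depth profiles, and grid-based population
    receptive field (pRF) eccentricity mapping. A synthetic-data module
    forward-models all three contrasts from known layer physiology so that every
    stage is verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
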
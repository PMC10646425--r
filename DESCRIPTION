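Package: vasoreact
Title: Blood-Pool MRI and Laser Doppler Assessment of Myocardial
    Microvascular Reactivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying myocardial microvascular vasomodulation
    from gas-challenge cardiac MRI acquired with a blood-pool contrast
    agent. Provides a digital short-axis cardiac phantom that simulates
    spoiled gradient echo (SPGR) acquisitions under a
    normoxia-hypercapnia-normoxia gas regime, variable flip angle (DESPOT1)
    T1 mapping, single-point post-contrast T1 inversion, per-ROI T1 time
    courses with gas-interval percent changes, laser Doppler flowmetry
    trace synthesis and analysis (perfusion, heart rate, motion-corruption
    flagging), and one-way ANOVA with Fisher's LSD post-hoc testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, MedicalImaging, Visualization, Regression
RoxygenNote: 7.3.3
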
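Package: fmisopet
Title: Pharmacokinetic Modelling of Dynamic 18F-FMISO PET for Tumour Hypoxia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying tumour hypoxia from dynamic 18F-FMISO PET.
    Implements the irreversible and reversible two-tissue compartment models with
    an exact piecewise-linear-input convolution solver, nonlinear least-squares
    fitting of time-activity curves with a residual-percentage goodness of fit,
    Gjedde-Patlak graphical analysis of the influx constant Ki, voxelwise Ki and
    k3 parametric mapping with tumour-overlap summaries, static tumour-to-blood
    hypoxia scoring, and a synthetic dynamic-PET phantom generator (2 h, 52-frame
    acquisition with a left-ventricle-style plasma input function and
    counting-statistics noise) so every stage is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
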
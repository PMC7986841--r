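Package: implantheat
Type: Package
Title: Combined Radiofrequency and Switched-Gradient Heating of Metallic
    Implants in MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale simulation pipeline for assessing the heating of
    metallic orthopaedic implants during MRI examinations. Synthesizes
    clinical pulse-sequence waveforms (TSE, EPI, GRE, TrueFISP) with
    whole-body SAR dead-time compliance; computes quasi-static eddy-current
    power deposition in the implant from the switched gradient fields via
    subsignal splitting and truncated harmonic decomposition; provides
    parameterised or imported radiofrequency power-density maps with
    perfect-conductor masking; solves the Pennes bioheat equation in
    temperature-increase form with nonlinear thermoregulation using a
    Douglas-Gunn time-split finite-difference scheme; and derives safety
    metrics (temperature-increase thresholds, heated tissue mass per tissue,
    time-to-threshold, distance-to-implant profiles) on voxelized phantoms
    with a simplified unilateral hip implant.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
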
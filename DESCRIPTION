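Package: bmerp
Title: Simulation and Analysis of ERP Responses to Point-Light Biological Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the electrophysiology of biological-motion
    perception end to end: parametric 13-marker point-light walkers with
    momentum-preserving scrambled controls and radial/lateral size-matched
    projections; a calibrated multi-subject 64-channel EEG epoch simulator
    (P1/N1 and early sustained negativity components, 1/f plus white noise,
    blink artifacts, behavioral responses); offline preprocessing (zero-phase
    band-pass, average reference, baseline correction, amplitude-threshold
    artifact rejection, spherical-spline bad-channel interpolation); ERP
    component measurement with repeated-measures ANOVA (Greenhouse-Geisser
    correction), Tukey HSD post-hocs and point-wise paired t-tests with a
    spatiotemporal contiguity criterion; polarity-sensitive topographic
    microstate segmentation with cross-validation model selection; and a
    miniature sLORETA source pipeline (analytic three-shell spherical forward
    model, standardized minimum-norm inverse, sign-flip permutation tests
    with max-statistic family-wise correction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
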
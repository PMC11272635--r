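Package: hipimpinge
Title: Hip Bone Impingement Simulation and Pelvic Tilt Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bone-on-bone femoroacetabular impingement on parametric
    hip models. Generates synthetic pelvis and femur surface meshes whose shape
    parameters (alpha angle, lateral center-edge angle, femoral and acetabular
    version, anterior inferior iliac spine morphotype) match a clinical cohort,
    poses the femur through activity-of-daily-living postures under anterior,
    neutral and posterior pelvic tilt, detects mesh collision, classifies the
    contact into acetabular regions, computes per-patient impingement incidence,
    and fits random-intercept linear mixed models (REML, Satterthwaite degrees
    of freedom, conditional AIC) quantifying the effect of posterior pelvic tilt
    adjusted for anatomy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    optparse
Config/testthat/edition: 3
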
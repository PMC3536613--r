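Package: refractory
Title: Refractoriness and Intermittent Control in Sustained Visuo-Manual Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates virtual participants tracking unpredictable double-step
    targets through zero-, first- and second-order (marginally stable or
    unstable) virtual systems, under either continuous predictive control or
    event-triggered intermittent control with a system-matched hold; estimates
    per-step response delays (RT1, RT2) by set-point reconstruction with a
    low-order zero-delay ARX model; and quantifies refractoriness with a
    repeated-measures ANOVA battery (averaged Greenhouse-Geisser/Huynh-Feldt
    sphericity correction), per-ISI post-hoc tests, and constrained and
    unconstrained RT2-versus-ISI regressions, classifying the triggering
    regime from the regression slope.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
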
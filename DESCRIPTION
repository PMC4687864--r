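Package: gaitwheel
Title: Gait Reconstruction and Classification from Force-Sensing Exercise Wheels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs single-limb vertical ground-reaction-force traces from
    multi-sensor Hall-voltage recordings of an instrumented rodent exercise wheel,
    extracts stride kinematics (stride frequency, stance period, duty factor, peak
    force), and scores gaits on a continuous stride-signal-symmetry (3S) scale with
    threshold calibration by sensitivity/specificity intersection. Includes a
    physics-based synthetic wheel-and-mouse signal generator (half-sine limb forces
    placed by Hildebrand footfall timings on a rotating 16-pad, 9-sensor wheel) so
    the full pipeline can be validated against known ground truth, plus
    Froude-number predictions of gait-transition speeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
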
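Package: pigspace
Title: Planimetric Measurement of Floor Area Covered by Finishing Pigs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrast-based planimetry for measuring the floor area physically
    covered by finishing pigs in thirteen standing and lying body postures from
    calibrated top-view images, together with a synthetic top-view scene
    generator with analytic ground truth (parametric silhouettes under a
    pinhole camera), allometric space-allowance models (a = k * W^0.66), the
    EU transport loading-density minimum (235 kg live weight per square
    metre), and the study-level statistics (Spearman correlations, Welch
    tests from summaries, Tukey-Kramer pairwise group comparisons with
    significance letters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
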
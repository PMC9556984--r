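Package: vaaflow
Title: Hemodynamic Analysis of Visceral Artery Aneurysm Formation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the hemodynamic environment in which visceral
    artery aneurysms form. Generates synthetic tubular vessel geometries with
    saccular or fusiform aneurysm bulges and stenoses, extracts
    arclength-parameterized centerlines with inscribed-radius profiles,
    performs virtual aneurysm excision with parent-artery reconstruction,
    synthesizes pulsatile wall shear stress fields from the analytic Womersley
    solution, computes wall-shear-derived indices (TAWSS, OSI, WSSG, AFI, peak
    WSS), compares aneurysm-forming against para-aneurysm vessel regions with
    area-weighted averages, and runs the associated statistical battery
    (Wilcoxon signed-rank normal approximation, two-sample t, Fisher exact and
    chi-square tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
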
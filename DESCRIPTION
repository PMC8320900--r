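Package: acuflow
Title: Alveolar Capillary Unit Network Perfusion and Filtration Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-to-model toolchain for subpleural lung microcirculation under
    hypoxic edemagenic stress. Generates ground-truthed synthetic intravital
    microscopy data, measures microvessel diameters from transect intensity
    profiles, builds two-dimensional alveolar capillary unit (ACU) networks by
    polygon-constrained Voronoi tessellation calibrated to a target
    capillary-to-interstitial volume ratio, solves steady Poiseuille network
    perfusion under arteriolar, venular and interstitial pressure boundary
    conditions with transmural-pressure dependent capillary de-recruitment, and
    computes Starling-law transcapillary filtration flow and surface across an
    edema time course.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    EBImage,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
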
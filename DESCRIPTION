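Package: bendmark
Title: Automated Landmarking of Bends in Vascular Centerlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective, automated subdivision of tubular vessel
    centerlines into bends, with the internal carotid artery (ICA) as the
    reference application. Provides centerline input/output (CSV and ASCII XML
    PolyData polylines), uniform resampling on a Catmull-Rom cardinal spline,
    iterative Laplacian smoothing, discrete curvature and torsion estimation,
    Frenet-Serret and parallel-transport frames, two landmarking algorithms
    (geometric bends bounded by torsion peaks, and anatomical four-bend
    subdivision of the carotid siphon driven by the curvature-vector trajectory),
    peak detection by topographic prominence, seeded synthetic centerline
    generators with designed ground truth, and coefficient-of-variation
    sensitivity and robustness sweeps over the preprocessing parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
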
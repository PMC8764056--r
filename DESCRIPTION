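Package: tortuometry
Title: Vessel Centerline Tortuosity Metrics and Low Wall Shear Stress Area Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional tortuosity measures (tortuosity index,
    total and average absolute-curvature, total squared-curvature, RMS-curvature,
    average squared-derivative-curvature) from vessel centerlines, quantifies the
    normalized surface area of triangulated vessel walls exposed to low
    time-averaged wall shear stress (TAWSS), and runs cohort-level statistics
    linking tortuosity to low-TAWSS area coverage: distribution shape
    (skewness, excess kurtosis), standardization, and per-metric linear
    regression with adjusted R-squared and significance classes. Includes a
    synthetic-cohort generator producing analytic curves, noisy centerlines,
    tubular surface meshes with TAWSS fields, and statistically structured
    cohort tables, so the full analysis runs without patient data. Reads and
    writes centerlines and surfaces as CSV and VTK PolyData (legacy ASCII and
    XML .vtp).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    generics,
    dplyr,
    e1071,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
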
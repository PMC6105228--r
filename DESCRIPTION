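Package: gravikine
Title: Space-Time Kinematics of Gravitropic Bending from Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the gravitropic response of rod-like plant
    organs (hypocotyls) from time-lapse bright-field and bioluminescence
    imaging. Extracts an arc-length-parameterized midline per frame by
    principal-curve analysis, computes deflection-angle, curvature and
    curvature-rate fields on the time-arclength plane with smoothing-spline
    derivative estimation, samples reporter luminescence at the median and
    at flank inset contours to form a differential-expression log-ratio
    (LRL), detects and angle-aligns response troughs, and selects between
    the sine-law and graviproprioception bending models by per-timepoint
    regression with AIC. Includes a forward simulator of graviproprioceptive
    rod bending with rendered image series and known ground truth for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    igraph,
    EBImage,
    tiff,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
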
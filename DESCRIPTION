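Package: aortamorph
Title: Micro-Scale Morphometry of the Aortic Wall from Phase-Contrast MicroCT Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying three-dimensional micro-scale
    remodelling of the murine aortic wall in phase-contrast micro computed
    tomography stacks. Segments the wall, lumen, tunica media and elastic
    lamellae on every transverse slice, estimates the vessel centreline and
    reslices the stack orthogonal to it, virtually opens the vessel by a local
    Cartesian-to-polar transformation, and measures per-slice lumen diameter,
    media thickness (with a Gaussian fit to the thickness histogram),
    cross-sectional areas and the medial fraction occupied by lamellae. The
    internal elastic lamina is extracted as a thin shell, projected en face and
    scored for surface breaks. Between-group comparisons use the two-sample
    Kolmogorov-Smirnov test and an F-test of dispersion. A synthetic aorta
    phantom generator with analytic ground truth supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    mgcv,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
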
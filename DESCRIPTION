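Package: hyperdim
Title: Hyperdimensional Imaging Microscopy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for hyperdimensional imaging microscopy (HDIM):
    a container for space x wavelength x polarization x photon-arrival-time
    photon-count histograms with calibrated axes, conservation-safe
    projections, per-pixel spectroscopic feature estimators (spectral peak,
    mean fluorescence lifetime, steady-state anisotropy), PCA contrast
    enhancement with digital HE-/DAB-like staining, a cluster separability
    statistic, and a photophysics simulator (Stern-Volmer quenching, Perrin
    depolarization, two-photon photoselection, Poisson counting) that
    regenerates a 12-solution FITC/R6G reference panel so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    rhdf5,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
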
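Package: fretmap
Title: Acceptor-Photobleaching FRET Analysis and Protein Proximity Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for acceptor-photobleaching FRET microscopy of
    multiprotein assemblies, built around the yeast endocytic coat use case.
    Provides a synthetic two-channel EMCCD microscopy simulator with ground
    truth, image and ROI input/output, per-cell and per-patch donor
    de-quenching FRET quantification with donor-only baseline correction,
    confidence-interval based FRET-positivity screening statistics,
    stage-resolved per-patch analysis sorted by a third-channel marker,
    FRAP recovery-curve fitting, and construction of a terminus-level
    proximity map with anchor-constrained axial layer assignment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
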
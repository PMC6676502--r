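Package: fluorquant
Title: Marker-Guided Quantification of Nuclear Immunofluorescence with
    Background Subtraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless pipeline for quantifying immunofluorescence intensity
    in nuclei. Segments nuclei on a marker channel of an RGB TIFF by
    thresholding and particle analysis (area and circularity filters,
    optional binary dilation and watershed splitting), transfers the
    resulting regions of interest onto a query channel, estimates background
    from the in-selection complement of the regions, and reports
    background-subtracted per-nucleus and per-image intensities as tidy
    tables and CSV files. Includes group-level fold-change, agreement and
    coefficient-of-variation statistics, a synthetic-image generator with
    known ground truth for validation, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
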
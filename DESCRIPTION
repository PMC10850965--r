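Package: wellcolor
Title: Digital Image Colorimetry for Well-Strip Assays in Cosmetic Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction-free quantification of analytes (illustrated by urea
    in oil-in-water cosmetic emulsions) from smartphone photographs of
    dye-treated formulation loaded in microstrip wells. Provides well
    localisation and region-of-interest extraction with glare/bubble pixel
    masking, per-well RGB and HSB channel statistics on the 0-255 ImageJ
    scale, in-matrix linear calibration with data-driven linear-range
    trimming and analytical-channel selection, direct and modified
    standard-addition quantification (extrapolation to a nonzero reference
    standard), validation statistics (intermediate-precision CV, bias,
    linearity), and a ground-truth synthetic plate-image simulator so the
    whole pipeline is testable without laboratory photographs.
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
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
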
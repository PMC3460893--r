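Package: prioralign
Title: Alignment of Conservation Land Acquisitions with Science-Based Priority Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a portfolio of land acquisitions (fee-simple
    purchases and conservation easements) matches priority areas identified by
    systematic conservation planning. Implements a planar vector-overlay
    pipeline (validity repair, equal-area projection, clip, dissolve,
    intersect), the science influence score (the excess of observed alignment
    over the alignment expected under area-proportional chance, normalised by
    its maximum), a centroid-based chi-square goodness-of-fit test against the
    area-fraction null, and a seeded synthetic-landscape generator that places
    parcels by a mixture process so both statistics can be validated by
    parameter recovery without access to sensitive land-holdings data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    polyclip,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    sp,
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
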
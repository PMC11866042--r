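Package: hecif
Title: Continuous Fibrosis Scoring of Bone-Marrow Trephines from H&E Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reticulin-free pipeline that quantifies bone-marrow fibrosis
    directly from H&E-stained trephine images as a continuous score (CIF,
    Continuous Indexing of Fibrosis). Provides a synthetic paired-stain
    phantom generator with known latent severity, tissue masking and tile
    extraction with composition filters, moment-based affine registration of
    co-sectioned stain pairs, channel-wise histogram equalisation, a
    pairwise ranking network that learns the fibrosis continuum from ordered
    tile pairs, slide-level stain and tissue quality control in RGB and
    CIELAB, and a subsampling-based fibrosis-heterogeneity and
    biopsy-adequacy analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    png,
    tiff,
    EBImage,
    generics,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
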
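Package: immunotopo
Title: Spatial Immune Topography of the Tumor Microenvironment from Multiplex IHC Label Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial relationship between tumor cells and immune
    infiltrates in multiplex immunohistochemistry (mIHC) segmentation masks of
    pancreatic ductal adenocarcinoma. Partitions the tumor-associated stroma into
    keratin-17-positive and keratin-17-negative influence zones by Euclidean
    distance transform, estimates intratumoral and peritumoral immune-cell
    densities (Tumor/Stromal Zone Scores), and provides cohort-level paired
    statistics, a randomization null for spatial enrichment, a dot-annotation
    segmentation-evaluation protocol, and a synthetic mask generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
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
    tools,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
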
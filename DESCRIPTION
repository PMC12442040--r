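Package: kendrickmsi
Title: Kendrick Mass Defect Analysis for MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organ-resolved lipid mapping from high-resolution
    MALDI-FT-ICR mass spectrometry imaging (MSI) data using Kendrick mass
    defect (KMD) analysis. Covers exact-mass arithmetic on elemental
    compositions, imzML reading and writing, peak picking and cross-pixel
    centroid alignment, KM/KMD computation and window filtering, CH2
    homologous-series and unsaturation/oxidation grouping, adduct and
    carbon-13 isotopologue collapsing onto protonated monoisotopic species,
    exact-mass lipid annotation against a bundled reference table, and ion
    image reconstruction with region-enrichment statistics. A synthetic
    "phantom organism" MSI generator with full ground truth makes the whole
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
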
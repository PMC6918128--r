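Package: aiflib
Title: AMRT+MS2 Spectral Library Construction from All-Ion-Fragmentation LC-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies accurate-mass plus retention-time plus MS2
    (AMRT+MS2) spectral libraries from all-ion-fragmentation (AIF) LC-MS
    dilution-series data. Provides exact-mass chemistry primitives (elemental
    formulas, adducts, isotopes), readers and writers for NIST MSP, MGF and
    MassBank record libraries, retention-time correction anchored on technical
    internal standards, MS2 spectral deconvolution by within-run least-squares
    fitting of elution profiles and by cross-dilution-series correlation,
    formula-based fragment/adduct/isotope annotation, library curation
    (grouping by InChIKey, consensus spectra, precursor m/z replacement,
    product-ion frequencies, library comparison), AMRT+MS2 identification of
    query features, and a ground-truthed synthetic AIF data generator for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
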
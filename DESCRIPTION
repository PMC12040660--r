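Package: sersclass
Title: Serum SERS Spectral Classification with PLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating patient groups from surface-enhanced
    Raman spectra (SERS) of blood serum. Implements the standard spectral
    preprocessing chain (Savitzky-Golay smoothing, iterative polynomial
    autofluorescence baseline removal, standard normal variate scaling), a
    from-scratch NIPALS partial least squares discriminant analysis (PLS-DA)
    with variable importance in projection (VIP), subject-grouped k-fold
    component selection, and a repeated stratified 80/20 split validation
    protocol with confusion metrics and ROC AUC. Includes a seeded synthetic
    SERS cohort generator so the full pipeline is testable without
    instrument data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
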
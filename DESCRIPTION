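Package: mdrank
Title: Prioritizing Disease-Related Microbes by Random Walk with Restart on a
    Heterogeneous Microbe-Disease Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a two-layer heterogeneous network from curated
    microbe-disease association catalogs, computes Gaussian interaction
    profile (GIP) kernel similarities for microbes and diseases, fuses the
    disease kernel with an external semantic disease similarity matrix, and
    prioritizes candidate disease-related microbes by random walk with
    restart over the composite transition operator. Includes leave-one-out
    and repeated five-fold cross-validation with per-disease ROC/AUC, a
    seeded synthetic catalog generator with planted community blocks for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
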
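Package: muscleclock
Title: Skeletal Muscle Epigenetic Clocks from Multi-Dataset DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds tissue-specific epigenetic clocks from heterogeneous
    collections of Illumina-style DNA methylation array datasets. Provides
    preprocessing (detection-based sample and probe filters, beta/M
    conversion, k-nearest-neighbour imputation, empirical-Bayes batch
    adjustment, cross-platform probe intersection), three-state beta-mixture
    quantile calibration of every sample to a gold-standard reference
    profile, elastic-net training of a transformed-age clock with
    leave-one-dataset-out evaluation and two age-acceleration statistics,
    an age EWAS with moderated-variance linear models and paired-design
    support, direction-consistent differentially methylated region calling,
    Fisher-exact and bias-aware (Wallenius) gene-set enrichment, a
    Monte-Carlo panel-overlap null, and a synthetic multi-dataset
    methylation simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    limma,
    sva,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
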
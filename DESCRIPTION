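Package: ggnforge
Title: Synthesis of Ground-Glass Nodules in Lung CT Slices with a
    Dual-Discriminator Generative Adversarial Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesising ground-glass nodules (GGNs) into masked
    lung CT slices with a generative adversarial network that judges both the
    whole image and the nodule region of interest, together with the full
    surrounding workflow: a seeded synthetic lung-phantom generator, the
    preprocessing chain (seed-filling lung segmentation, background stripping,
    intensity normalisation, nodule erasure into training pairs), a
    structural-similarity plus adversarial composite loss, an adversarial
    training loop with checkpointing, a 93-feature radiomics extractor over
    six standard feature families, per-feature two-sample Kolmogorov-Smirnov
    cohort comparison, cross-validated real-versus-synthetic classification,
    visual-Turing-test analytics, and a data-augmentation sweep measuring how
    synthetic nodules change classifier precision and recall as a function of
    the real-data fraction.
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
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
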
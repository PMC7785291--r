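Package: dynapstats
Title: Enrichment Scoring and Imaging Statistics for Dynein-Assembly Organelle Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative toolkit for studying the cytoplasmic organelles in
    which axonemal dyneins are pre-assembled (DynAPs) in multiciliated cells.
    Implements spectral-count enrichment scoring of affinity-purification
    mass-spectrometry (APMS) pulldowns against GFP-only controls (orthogroup
    collapsing, pseudocounted log2 fold-change, one-sided Z-test,
    Benjamini-Hochberg FDR), fluorescence-recovery-after-photobleaching
    (FRAP) trace normalization and single-exponential recovery fitting with
    mobile fraction and half-time, Pearson colocalization within region-of-
    interest masks of two-channel z-stacks, and intensity profiles along the
    normalized axoneme length ratioed to a membrane reference channel. A
    synthetic-data module generates all pipeline inputs with known ground
    truth: multinomial PSM pulldown tables, FRAP traces with acquisition
    photobleaching, two-channel foci phantoms with tunable sub-structure
    overlap, and axoneme phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
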
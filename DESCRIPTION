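Package: dhquant
Title: Marker-Guided Densitometry and Expression Summaries for the Spinal Dorsal Horn
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the regional distribution of an immunolabelled target
    (e.g., the CB1 cannabinoid receptor) across the superficial and deeper
    spinal dorsal horn. Provides marker-guided region-of-interest
    segmentation from a CGRP-like landmark channel, background-normalized
    optical-density measurement with technical-replicate averaging and
    SDH/DDH localization ratios, an assumption-gated nonparametric test
    battery (exact and asymptotic Wilcoxon signed-rank and Mann-Whitney U,
    one-way ANOVA, and a two-way aligned rank transform ANOVA), and a
    single-cell RNA-seq dot-plot summarizer (counts-per-million averages,
    percent expressed, z-scored color values over pooled laminar cluster
    groups). Includes generators for synthetic two-channel section phantoms
    and clustered negative-binomial count matrices so the full pipeline is
    testable without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    car,
    ggplot2,
    jsonlite,
    methods,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
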
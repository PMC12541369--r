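Package: meiofoci
Title: Quantification of Meiotic Recombination Foci, Shape-Model Selection and
    Crossover Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for meiotic recombination studies in
    C. elegans germlines. Classifies single-molecule localization microscopy
    (SMLM) point clouds of late recombination foci as hollow elliptical rings
    or filled ellipses by maximum-likelihood fitting and small-sample-corrected
    AIC (normAICc) model selection; detects and classifies diffraction-limited
    foci (singlets, elongated singlets, doublets, triplets) anchored to
    crossover-designation sites within a colocalization radius; maps crossovers
    from ordered SNP marker genotypes and computes per-interval and overall
    recombination frequencies; and provides the cohort statistics (two-sided
    Fisher's exact test, Mann-Whitney U, viability and zone-wise focus-count
    summaries) connecting them. Synthetic-data generators emulate every input
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    withr,
    pracma,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
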
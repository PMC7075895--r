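Package: speechcontrast
Title: Speech-Based Detection of Drug-Induced Mental States by
    Paired-Contrast Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting acute drug-induced mental
    states from speech in within-participants crossover designs. Extracts
    acoustic (jitter, shimmer, harmonics-to-noise ratio, pitch, pauses,
    MFCCs, formant vowel space), semantic (latent semantic analysis
    concept proximity), and psycholinguistic (propositional idea density,
    lexical richness) features from recordings and transcripts; classifies
    drug conditions within subject via signed feature-difference contrasts
    under nested leave-one-participant-out cross-validation; and provides
    group-level paired nonparametric tests with false-discovery-rate
    control, regularized partial-correlation structure, and
    multidimensional scaling. Includes a fully seeded synthetic cohort
    generator (source-filter voice synthesis plus topic-model transcripts)
    with known planted effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    ranger,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    class,
    e1071,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
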
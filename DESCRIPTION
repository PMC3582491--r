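Package: apppre
Title: Effect Sizes and Cross-Species Conservation for the APP Promoter
    Proximal Regulatory Element
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the 30-nucleotide proximal regulatory
    element (PRE, -76/-47 from the transcription start site) of the amyloid
    precursor protein (APP) gene promoter. Standardizes densitometric gel
    shift (EMSA) and reporter ELISA replicate measurements, computes
    bias-corrected Hedges g effect sizes with a shared ANOVA mean square
    error, the assay-level root-mean-square standardized effect, and
    Dunnett's multiple-t comparisons against wildtype; correlates paired
    effect sizes across assays with bootstrap inference and bootstrap
    distribution overlap; performs taxonomically weighted conservation
    analysis of an aligned promoter region (working weights, per-column
    information content in bits, 100-nt window tracks, weighted homology,
    sequence-logo matrices); classifies root-to-tip molecular-clock
    outliers on a rooted phylogeny; and scans PRE variants against a
    literal transcription-factor binding-site catalog. Includes seeded
    synthetic-data generators emulating each stage's inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nortest,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
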
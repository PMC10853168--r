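Package: hapscore
Title: HLA Tumor-Antigen Presentation Scoring for Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the capacity of a patient's HLA class I genotype to
    present tumor neoantigens and relates it to immune-checkpoint-inhibitor
    outcome. Implements HLA-I evolutionary divergence from Grantham amino-acid
    distances over the aligned peptide-binding domain, neoantigen burden
    scoring from MHC-I binding predictions, the combined HLA tumor-Antigen
    Presentation Score (HAPS) with survival-based cut-off scanning, HLA
    loss-of-heterozygosity stratification, TCR beta CDR3 repertoire metrics
    (Shannon diversity, clonality, edit-distance summaries, substitution
    networks), a neoantigen quality score, cytolytic-activity scoring, and a
    single-hidden-unit neural network integrating presentation, mutational
    burden and T-cell diversity into a response classifier. A seeded synthetic
    cohort generator exercises the full pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
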
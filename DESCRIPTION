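Package: isopull
Title: Quantitative Interactomics from Stable-Isotope-Labeled Pull-Down Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel (14N/15N) affinity-purification
    mass-spectrometry interactome experiments that use a triple-sample design
    (WT/WT control, Bait/WT experiment, Bait/Bait control). Takes peptide-level
    heavy/light ratio reports, inverts and median-normalizes ratios per run so
    the nonspecific background is centered on 1, applies stringent ion- and
    protein-level quality filters (q-value, ion CV, data completeness, sequence
    coverage, peptide count) with a bait-inclusion tuning loop, aggregates
    peptides to proteins by the median, fits an empirical-Bayes moderated
    one-sample t-test on log2 ratios with Benjamini-Hochberg correction, and
    classifies specific bait interactors using the control samples to exclude
    nonspecific and artifactual enrichment. Includes 15N labeling mass
    arithmetic (per-peptide nitrogen counts and heavy precursor m/z) and a
    synthetic-data simulator with ground truth so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    ggplot2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
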
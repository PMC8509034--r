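Package: plfr
Title: Peptide Location Fingerprinting for Spectral-Count Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects regional structural differences in proteins from
    label-free proteomics by peptide location fingerprinting (PLF):
    peptide spectral counts are mapped onto fixed-size (50 amino acid)
    segments of each protein's primary structure, normalised for
    whole-protein abundance against the experiment-wide median spectrum
    count, averaged per group, and compared segment by segment between
    two groups with per-protein Bonferroni correction. Includes
    cross-tissue-region set comparison of flagged proteins, composite
    profile scaling for multi-region overlays, a seeded synthetic-study
    generator (tryptic digestion, overdispersed spectral counts,
    implanted region-specific yield perturbations) for validation and
    power analysis, and tidy/ggplot2 interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
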
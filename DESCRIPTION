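Package: immunodominance
Title: Immunodominance Analysis of Epitope-Specific CDR3 Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing immunodominant (ID) and subdominant (SD)
    T cell responses from epitope-specific CDR3 clonotype tables in the
    VDJdb tab-separated dialect. Parses clonotype records with JSON-embedded
    subject metadata and frequencies, labels each subject's top clone as the
    immunodominant response, extracts the non-germline (non-VJ) CDR3 region
    by exact V/J prefix-suffix trimming, computes a physicochemical feature
    panel (Kyte-Doolittle hydropathy, polarity, bulkiness, aliphatic index,
    net charge, Boman index, ten Kidera factors), builds fixed-width
    IMGT-anchored CDR3 alignments, and derives positional probability
    matrices and the capped positional log enrichment score (pLES) between
    ID and SD sets. Includes a synthetic repertoire generator with ground
    truth for end-to-end validation, and distributional test helpers
    (Kolmogorov-Smirnov, Mann-Whitney, Shapiro-Wilk, Spearman, and a
    k-sample Anderson-Darling test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
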
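Package: gillzinc
Title: Time-Course Transcriptomic Analysis of Zinc Depletion in the Fish Gill
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel (sample versus common reference)
    microarray time courses of the zebrafish gill under zinc depletion.
    Implements MA transformation and lowess normalization, per-spot confidence
    and minimum-replicate filtering, per-time-point differential-expression
    calling (Welch t-test, Benjamini-Hochberg false-discovery-rate control,
    signed fold-change thresholding), temporal regulation summaries,
    annotation-term enrichment by the one-sided Fisher exact test and its
    conservative EASE variant, promoter extraction and IUPAC consensus
    transcription-factor-binding-site scanning with a two-proportion z-test
    against a non-regulated control cohort, curated direct-interaction-network
    assembly with hub ranking, and the closed-form physiological calculations
    (unidirectional ion influx, qPCR standard-curve quantification). A
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
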
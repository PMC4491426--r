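Package: oginet
Title: Outcome-Guided Mutual Information Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies gene pairs whose joint state carries information
    about a binarized clinical outcome, using an extended mutual
    information score I(X1,X2;Y) on histogram-discretized genomic
    profiles.  Significance is assessed non-parametrically via a
    label-permutation threshold; significant pairs are assembled into
    per-profile outcome-guided networks which can be integrated across
    molecular levels (expression, copy number, methylation) by edge
    intersection or union.  Detected pairs are validated with MDR-style
    high/low-risk stratification followed by log-rank survival tests and
    Kaplan-Meier curves, and networks are summarized topologically
    including a log-log regression index of scale-freeness.  Includes a
    synthetic multi-profile data generator with planted interaction pairs
    and censored survival outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
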
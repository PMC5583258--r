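Package: vocalexchange
Title: Mother-Infant Vocal Exchange Analysis for Nest Reunion Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing vocal turn-taking between mothers and
    infants around nest entries and exits. Extracts one-minute Reunion and
    Leave-taking observation intervals from nest-occupancy records, assigns
    annotated call events to intervals, classifies per-interval exchange
    patterns (reciprocal, sequential, antiphonal calling, initiator and call
    timing), aggregates per-family summaries, and runs the group-level
    nonparametric statistics (Wilcoxon signed-rank tests with exact and
    asymptotic p-values, optional binomial mixed model). A point-process
    simulator generates synthetic study data with known ground truth so the
    whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
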
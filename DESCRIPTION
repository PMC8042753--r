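Package: dupdiverge
Title: Functional Divergence Scoring and Evolutionary Analysis of Duplicate Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the degree of functional divergence (DFD) of duplicate
    gene pairs from protein-coding sequence divergence (KA/KS, Nei-Gojobori
    1986 counting with Jukes-Cantor correction) and expression-profile
    similarity (Spearman Re normalised by KS), fits a logistic model for the
    probability that a pair is highly diversified, calibrates high/low
    decision thresholds at a fixed false-positive rate, and runs the
    downstream functional-bias, ortholog-retention and branch-specific
    selection analyses. A seeded synthetic-data generator produces codon
    sequences evolved under specified selection intensity, correlated
    expression profiles, annotations and ortholog triplets so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
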
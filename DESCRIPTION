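Package: nniomics
Title: Deductive Epitope Mapping by Motif Sifting, Chance-Match
    Probability and Preabsorption Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deducing a polyclonal antibody's epitope from
    indirect evidence: proteome-wide short-linear-motif census with a
    composition-based Method-of-Exclusion filter, exact chance-match and
    partial-anagram probability calculus over residue multisets,
    chi-squared comparison of peptide conformer interatomic-distance
    tables, and quantitative analysis of immunohistochemistry
    preabsorption panels (percent-of-control staining, unpaired t-tests,
    IC50 bounds, suffix-pattern epitope inference). Includes seeded
    synthetic-data generators (proteomes with planted motifs, jittered
    distance tables, dose-response panels, thresholded images) so every
    analysis is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
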
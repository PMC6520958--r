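Package: algapept
Title: In Silico Screening of Algal Bioactive Peptides
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the in silico screening cascade used
    to characterise ACE-I inhibitory peptides from the green macroalga Ulva
    lactuca: monoisotopic/average peptide mass and m/z calculation, Ney Q-rule
    bitterness prediction, simulated gastrointestinal digestion by a
    declarative P4-P4' context-window cleavage-rule engine (pepsin at pH 1.3
    and pH > 2, trypsin, chymotrypsin), exact matching of released fragments
    against a bundled bioactive dipeptide/tripeptide reference, auto- and
    cross-covariance (ACC) descriptor transformation with 1-nearest-neighbour
    allergenicity classification, toxicity thresholding of SVM scores, and the
    ACE-I/renin inhibition assay formulas. Ships the 48 LC-MS/MS-identified
    peptides and the downstream ground-truth tables as plain-text fixtures,
    plus seeded synthetic-data generators so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
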
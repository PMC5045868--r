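Package: belminer
Title: Extraction, Validation and Scoring of Biological Expression Language Statements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for turning biomedical text plus controlled
    vocabularies into Biological Expression Language (BEL) statements. Provides
    a parser, canonicalizer and syntax/semantic validator for the BEL statement
    subset used in sentence-level curation; dictionary-based named entity
    recognition with longest-match harmonization and organism ranking; a
    BioNLP-ST event model with standoff input/output and baseline trigger-lexicon
    extractors; rule-based translation of events and co-occurrence pairs into
    BEL statements; multi-level scoring of predicted against gold statements
    (term, function, relationship and full-statement levels); and a curation
    document model with BELScript export gated on validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
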
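Package: maplint
Title: Automated Failure Detection for Biomedical Concept Mapping of
    Online Community Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An audit battery for the output of biomedical concept mappers
    (such as MetaMap) run over patient-generated online-community text.
    Detects boundary failures (single coherent phrases split into multiple
    concepts), missed-term failures (community-specific abbreviations and
    misspellings left unmapped, recovered by expansion/spell-correction and
    differential re-mapping), and nine causes of word-sense-ambiguity
    failures (contractions with multiple parts of speech, colloquial
    language mapped to gene concepts, dates and times, email addresses and
    URLs, Internet slang, personal names, the narrative pronoun "I",
    mismapped verbs, and inconsistent concept assignments). Aggregates
    failures with unique-failure accounting, supports stratified sampling
    for blind manual evaluation with confusion-matrix metrics, and ships a
    synthetic corpus generator with ground-truth labels plus a worked
    example fixture. External taggers, chunkers, spellers and mappers plug
    in through simple function contracts; deterministic lightweight
    defaults are bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
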
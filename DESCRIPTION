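Package: odmsim
Title: Semantic Comparison of CDISC ODM Study Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses CDISC ODM 1.3.1/1.3.2 study-metadata files whose items
    carry UMLS concept annotations, classifies every item pair into one of
    six similarity levels (NOTCODED, DIFFERENT, SIMILAR, TRANSFORMABLE,
    MATCHING, IDENTICAL), and renders content summaries, per-level pair
    listings and a comparable-items matrix supporting form-set versioning,
    cross-institution comparison and secondary-use screening. Includes a
    deterministic generator of ODM fixtures with planted relationships, a
    structural validator, System Usability Scale scoring utilities and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
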
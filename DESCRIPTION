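Package: suppminer
Title: Mining Biodata Resource Names and Accession Numbers from Article
    Supplementary Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining mentions of Global Core Biodata Resources
    (GCBRs) in the supplementary data files of open-access articles.
    Classifies the files of a PMC-style article bundle into manuscript
    and supplementary material, extracts plain text from spreadsheets,
    word-processor documents, PDFs, delimited text and markup files,
    recognizes resource names (dictionary matching with word boundaries)
    and accession numbers (identifiers.org-style Local Unique Identifier
    patterns with prefix forcing for over-general patterns), deduplicates
    mentions at the article level across the MEDLINE, full-text and
    supplementary collections, and tabulates per-resource, per-year and
    per-filetype counts. A synthetic-corpus generator produces fully
    self-contained article bundles with planted mentions, decoy strings
    and deliberately corrupted files, so the whole pipeline is testable
    without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readxl,
    stringi,
    tibble,
    tools,
    utils,
    withr,
    xml2,
    yaml,
    zip
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
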
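Package: barcodeid
Title: Molecular Species Identification from Local BLAST Searches
    Against a Reference Sequence Library
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the routine DNA-barcoding workflow of searching query
    sequences against a curated Reference Sequences Library (RSL) with local
    blastn, parsing the extended 16-field tabular output, filtering hits by
    query coverage and alignment length, retrieving the best match per query,
    tagging identifications that fall below a similarity threshold derived
    from the interspecific divergence of the marker, attaching user-supplied
    taxon-specific warnings, and writing a four-sheet spreadsheet report.
    The filtering and reporting core also runs on pre-computed hit tables,
    without the external aligner. Includes a synthetic-fixture generator
    (reference libraries, point-mutated queries with known identity, hit
    tables) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    digest,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
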
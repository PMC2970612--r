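Package: boolmerge
Title: Boolean Integration of Heterogeneous Annotation Tables with
    Fingerprint-Hash Alias Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A standalone engine for merging heterogeneous tabular
    datasets (gene lists, annotation tables, drug-target maps) with
    Boolean set algebra: intersection, union and left-relative
    subtraction over entity groups rather than raw identifier strings.
    Identifiers that name the same underlying entity under different
    nomenclatures are reconciled through an alias registry keyed by
    160-bit fingerprint hashes (of sequences, chemical formulas or
    URIs); identifiers are consolidated into entity groups by exact
    string matches and shared hash keys, closed transitively.  Includes
    a query grammar with documented operator precedence, touch-point
    switching to re-key a table on a different column, a seeded
    synthetic fixture generator for verification at benchmark scale,
    and a command-line interface over a local workspace.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    digest,
    igraph,
    jsonlite,
    utils,
    stats,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
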
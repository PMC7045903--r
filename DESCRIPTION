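Package: s6lift
Title: Selling-Scalar (S6) Lattice Representation and 3x3 to 6x6
    Transformation Lifting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with crystallographic lattices in the
    six-dimensional space S6 of Selling scalars.  Converts unit cells
    between parameter form, edge-vector bases and S6 vectors; lifts any
    3x3 unit-cell transformation matrix to the mathematically equivalent
    6x6 matrix acting on S6 vectors via six degenerate basis cells;
    performs Selling reduction to the all-nonpositive-scalar domain while
    tracking the accumulated transformation in both spaces; and ships the
    catalog of the 24 canonical Delone types with their primitive-to-
    centered transformation matrices in both E3x3 and S6.  Includes a
    command-line interface and parsers for plain-text, JSON and PDB
    CRYST1 cell input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
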
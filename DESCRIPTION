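Package: glycanid
Title: Nine-Digit Identifiers for Mammalian N-Glycans
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the nine-digit numeric encoding of mammalian
    N-glycan structures: parsing, validation and normalisation of
    identifiers; expansion of codes into explicit residue/linkage trees;
    conversion to and enumeration from GlycoBase-style abbreviations
    (e.g. A4G4FLac1S3); rendering in CFG and Oxford symbol notations to
    SVG and PNG/JPEG/BMP; batch grids of structures from code-list files
    and multi-set alignment for visual comparison; and enumeration of
    single-enzyme glycosyltransferase/mannosidase transitions between
    codes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: grDevices, graphics, utils, optparse
Suggests: testthat (>= 3.0.0), png, xml2, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
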
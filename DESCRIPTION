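Package: plasmidkit
Title: Headless Plasmid Editing, Annotation, and In Silico Cloning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for everyday plasmid work: a DNA record model
    with GenBank flat-file input/output (including the ApEinfo display
    dialect), degenerate-pattern feature libraries for automatic annotation,
    restriction-site search with methylation blocking, full and partial
    digests rendered as virtual agarose gels, simulators and designers for
    restriction ligation, Golden Gate, Gibson, and recombinase-mediated
    assembly, primer binding-site search and PCR simulation, dCAPS genotyping
    assay design, and anchored global alignment with affine gap penalties.
    Tabular results are returned as tibbles; gels and maps plot with ggplot2
    or render to SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    stringr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    xml2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
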
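Package: snailplot
Title: Snail Plots and Snail Scores for Genome Assembly Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes genome assembly quality statistics (span, Nx, auN and
    N-adjusted auN, GC/AT/N composition, BUSCO completeness) from an assembly
    FASTA and optional BUSCO full table, derives the scale-independent "snail
    score" (adjusted relative auN) together with its expected-genome-size
    corrected variants, and renders the layered circular snail-plot assembly
    badge as SVG. Includes a minimal BlobDir-style JSON dataset reader/writer,
    a scaffold filter grammar, a deterministic synthetic-assembly generator
    for testing, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    xml2,
    optparse,
    stats,
    tools,
    utils
Suggests:
    rsvg,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
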
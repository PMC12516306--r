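Package: dotquilt
Title: Triangular-Matrix Dot Plots of Pairwise Local Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Visualizes local alignments among multiple annotated DNA
    sequences as pairwise dot plots arranged into a single upper- or
    lower-triangular matrix. Consumes minimap2/MashMap PAF and LastZ
    general-format alignments (computing them with an external aligner and
    caching the raw output for reuse), orients every sequence relative to
    the first, colors alignment segments by percent identity over a
    clamped colormap range, draws BED annotation tracks and breakpoint
    guide lines, and writes publication-ready PNG and PDF figures. A
    seeded synthetic-locus generator with exact ground-truth alignments
    supports end-to-end testing without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    grDevices,
    grid,
    jsonlite,
    optparse,
    stats,
    tibble,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
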
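Package: homeallele
Title: Homoeallelic Base Assignment in Allopolyploids from RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Genome-wide assignment of homoeallelic base identities to
    allopolyploid subgenomes at homeolog-specific polymorphism (HSP)
    positions. Read pairs aligned to a transcriptomic reference are turned
    into base patterns over HSP sites, denoised, optionally merged by
    overlap, and assigned to subgenomes by percentage identity with diploid
    progenitor substitution profiles; a position-wise election then assigns
    a base per subgenome, tolerating one missing diploid progenitor.
    Includes construction of concatenated in-silico transcriptomic
    references, per-base coverage counting with mapping-quality and
    mate-pair filters, HSP/SBS validation against coverage, a deterministic
    allopolyploid read simulator with truth tables, call-set comparison
    utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    rtracklayer,
    tibble,
    utils,
    stats,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
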
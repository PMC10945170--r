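Package: locusharvest
Title: Sequence Mining, Screening, and Supermatrix Assembly for
    Multilocus Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns a local snapshot of heterogeneous sequence records
    (FASTA plus tabular metadata and BLAST-style tabular search hits)
    into a clean, partitioned, species-level concatenated matrix.
    Resolves published organism names against a user-supplied synonymy
    table, filters and assigns search hits to bait loci, selects the
    representative sequence per species and locus by unambiguous DNA
    content, screens cross-family contamination at a percent-identity
    threshold, tiles sequence fragments along bait loci with a
    fewest-tiles/highest-coverage objective, collapses copies into
    IUPAC consensus sequences, grafts barcode loci between conspecific
    specimens, and concatenates per-locus alignments into a partitioned
    supermatrix with occupancy reporting.  Includes a seeded synthetic
    snapshot generator with planted ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
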
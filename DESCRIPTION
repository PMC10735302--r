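Package: orthostitch
Title: Reference-Guided Stitching of Protein-Coding Markers from Fragmented
    Assemblies and Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines protein-coding phylogenetic markers (for example
    single-copy ortholog sets) from fragmented genome assemblies or raw
    sequencing reads. Translated-search hits against reference proteins are
    merged by a stack-based hit-stitching algorithm that realigns
    overlapping regions and keeps the best-scoring segment at each overlap.
    Stitched sequences are masked (insertions, ambiguous residues, stop
    codons), trimmed with a sliding-window gap-excluded identity filter,
    concatenated and realigned to the reference, and summarised with
    per-marker and aggregate recovery statistics. Includes a built-in
    six-frame translated search, parsers for external tabular search
    results, a synthetic fixture generator with known ground truth, and a
    paired-end read subsampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
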
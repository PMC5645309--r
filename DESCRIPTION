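Package: fourcmap
Title: 4C-Seq Viewpoint Contact Maps, Permutation-FDR Interaction Calling
    and Enhancer Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for circular chromosome conformation capture
    sequencing (4C-seq) viewpoint analysis: in-silico restriction digestion
    into fragment maps, bait demultiplexing and primer/quality trimming of
    paired-end reads, exact-match alignment and per-fragment quantification
    with self-ligation, uncut and non-ligated-control filters, RPM-normalised
    running-window contact profiles, permutation-FDR significant-interaction
    calling with robustness categories, replicate reproducibility, and
    enhancer-candidate annotation from transcription-factor co-binding
    clusters. Includes a seeded synthetic 4C-library generator with known
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
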
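Package: telandscape
Title: Transposable Element Landscapes from RepeatMasker Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of transposable-element (TE) annotations for
    compact genomes such as those of birds. Parses RepeatMasker-style
    annotation files, classifies repeats into a configurable TE taxonomy
    (SINE, LINE with CR1/R2/RTE clades, LTR with ERV1/ERV2/ERV3 classes,
    DNA transposons), computes overlap-resolved genome coverage, converts
    copy divergence to Jukes-Cantor substitution levels and insertion ages
    (t = K/2r), and builds binned age landscapes per TE class. Repeat
    libraries can be deduplicated with the 80-80 family rule and candidate
    LINE/ERV elements screened for intactness (ORF1/ORF2 and GAG/POL/ENV
    domains). A synthetic-data generator emits toy genomes, annotations,
    libraries and elements with full ground truth so every pipeline stage
    is testable without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
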
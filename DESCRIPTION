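Package: spsarch
Title: Su(H) Paired-Site Regulatory Architecture Scanning and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies paired Suppressor of Hairless (Su(H))
    binding-site architectures (SPS and SPS+A modules) in genomic contigs of
    the Enhancer of split complex and related Notch-regulated loci.
    Provides degenerate IUPAC motif compilation and exhaustive both-strand
    scanning, inverted-pair construction with spacer and Y-position typing,
    gene-relative positioning over non-coding DNA, 3' UTR Brd/GY/K box
    profiling with cross-species organization comparison, flank extraction
    with global affine-gap alignment and percent identity, and a seeded
    synthetic-contig generator that plants whole regulatory architectures
    with machine-readable ground truth for recall and false-positive
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
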
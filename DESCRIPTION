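Package: orthostress
Title: Cross-Species Orthogroup Classification of Stress-Responsive Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares differential-expression responses across species at the
    orthogroup level. Calls differentially expressed genes from fold-change and
    FDR tables, summarises per-orthogroup response directions with a
    mixed-direction exclusion rule, classifies conserved and opposite responses
    between species, and applies k-of-n multi-treatment filters. Scans 2 kb
    promoter regions for degenerate IUPAC cis-elements such as the
    mitochondrial dysfunction motif (CTTGNNNNNCAMG), tests motif enrichment by
    chi-square against an expressed-gene background, and filters mitochondrial
    dysfunction stimulon candidate genes. Provides hypergeometric and Fisher
    over-representation tests for transcription-factor families and functional
    categories, and a synthetic-data generator that plants known orthogroup
    response classes and promoter motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
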
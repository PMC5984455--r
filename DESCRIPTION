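Package: epitempo
Title: Temporal m6A Epitranscriptome Analysis from MeRIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for temporal analysis of N6-methyladenosine (m6A)
    epitranscriptomes from MeRIP-seq (m6A-seq) experiments: read
    preprocessing (adapter and quality filtering), peak-level IP/input
    enrichment scoring with FPKM-style normalization, peak retention
    filtering, cross-stage merged peak atlases, ON/OFF methylation
    switches across adjacent developmental stages, continuously and
    specifically methylated RNA (CMR/SMR) classification, differential
    methylation between conditions, metagene peak-distribution profiles
    with codon-anchored windows, and a methylation-expression
    correlation screen. Includes a synthetic MeRIP-seq generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
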
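Package: tfcoop
Title: Inference of Cooperative Transcription Factor Pairs from Promoter
    Binding-Site Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies potentially cooperative transcription factor (TF)
    pairs from promoter sequences. Binding sites are predicted with
    MATCH-style position weight matrix scanning (information-weighted core
    and matrix similarity scores on both strands), co-occurrences of
    heterotypic sites within a 5-20 bp gap window are counted across
    promoters, and pair cooperation is scored by pointwise mutual
    information corrected against a background estimated from
    dinucleotide-preserving shuffled promoters (PMIcor with scaling factor
    alpha). Pairs with z-score >= 3 form phenotype-specific cooperation
    networks that can be compared for common edges, phenotype-specific
    edges and partner-switching TFs. Includes a synthetic promoter corpus
    generator with planted cooperative motif pairs for benchmarking, plus
    readers for TRANSFAC and JASPAR motif formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
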
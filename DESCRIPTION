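Package: haplodag
Title: Reference-Based Diploid Haplotype Phasing with a Haplotype DAG
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Read-backed phasing of heterozygous SNPs and short INDELs in a
    diploid sample. Variants become sibling node pairs (levels) of a haplotype
    directed acyclic graph; aligned read fragments create counted, directed
    edges between adjacent levels, discontinuous paired-end fragments induce
    edges across coverage gaps by a look-ahead pre-order depth-first traversal,
    and each connected block is phased by the minimum negative log-likelihood
    path through the graph. Includes a phased-VCF/block writer, switch-error
    and N50 evaluation against a truth-phased VCF, and a seeded diploid read
    simulator that emits standard FASTA/VCF/SAM inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
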
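Package: orthofill
Title: Ortholog-Guided Transcriptome Curation, Reconstruction and
    Pseudogene Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with fragmented de novo plant
    transcriptome assemblies against a conserved reference ortholog set:
    curation of redundant assemblies to representative contigs with ORF
    and completeness statistics, FPKM quantification with
    correlation-distance hierarchical clustering and bootstrap replicate
    quality control, ortholog-guided stitching of fragmented contigs
    into full-length coding sequences with iterative exact-match read
    gap filling, six-frame translated recovery of unannotated genes from
    genomic scaffolds, and a pseudogenization scanner that calls
    frameshift indels, premature stop codons and retained introns
    relative to a reference ortholog. Includes a synthetic-data module
    that generates gene models, diverged orthologs with planted events,
    reads and clustered count matrices with machine-readable ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
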
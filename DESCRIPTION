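Package: misincmap
Title: Misincorporation Mapping of Hard-Stop RNA Modifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects hard-stop RNA modifications such as N1-methyladenosine
    (m1A) from multi-replicate aligned RNA-seq by mapping reverse-transcriptase
    misincorporations: per-replicate pileups with UMI-aware duplicate
    collapsing and end clipping are filtered by combined read depth,
    misincorporation rate, cross-replicate reproducibility and mismatch
    heterogeneity, with variant masking to exclude SNPs. Also provides
    truncation-signature analytics for antibody CLIP libraries (termination
    profiles around transcription-start sites, stacked-read cluster calling, a
    simplified RNA-seq-normalised metagene, and start-nucleotide enrichment
    testing), a curation workflow for external modification-site lists, and a
    seeded read simulator that plants modifications, SNP and editing decoys so
    the whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
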
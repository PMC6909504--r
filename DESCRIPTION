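Package: imprintseq
Title: Allele-Specific Chromatin Analysis of Imprinted Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for allele-specific chromatin organisation at
    imprinted loci: CTCF ChIP-seq peak calling on 50-bp bins with input-based
    blacklisting and quantile normalisation, allelic (>= 3-fold differential)
    peak calls, per-restriction-fragment 4C-seq quantification with window
    normalisation, sub-domain signal distributions and a fragment-fraction
    G test of independence, ICE balancing and insulation-index TAD-border
    calling on binned contact matrices, a compound TPM detection and
    differential-expression filter for mono-parental samples, and 3D DNA-FISH
    inter-probe distance statistics with an exact Mann-Whitney test. Includes
    a seeded synthetic-data generator that emulates an imprinted domain
    (planted mono-allelic peaks, a maternal-specific sub-TAD, SNP-bearing
    reads of known parental origin) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
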
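Package: balsel
Title: Balancing-Selection Genome Scan with Coalescent Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting long-term balancing selection from
    phased population resequencing data. Implements a folded allele-frequency
    correlation statistic (beta) standardised by locus-specific Watterson theta,
    with an empirical control-gene outlier null; a maximum-likelihood HKA
    polymorphism/divergence test with a per-locus selection parameter; sliding
    window diversity statistics (pi, Watterson's theta, Tajima's D) with
    mask-corrected effective lengths; D-prime haplotype blocks (Gabriel
    confidence-interval method) and median-joining haplotype networks; and a
    structured-coalescent simulator of neutral and balanced loci so that every
    stage is verifiable against closed forms without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    IRanges,
    rtracklayer,
    igraph,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
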
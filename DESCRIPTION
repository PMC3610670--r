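Package: haploscan
Title: Extended Haplotype Homozygosity Scans for Selective Sweeps in Phased SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects signatures of recent positive selection in phased
    biallelic SNP panels with the extended haplotype homozygosity (EHH)
    framework. Core regions are identified as contiguous runs of SNPs in
    strong linkage disequilibrium via profile-likelihood confidence
    intervals on D-prime, core haplotypes are enumerated within each
    region, EHH decay profiles and relative EHH (REHH) are evaluated at a
    matched genetic distance, and significance is assigned within
    core-haplotype frequency bins. Downstream utilities extend significant
    regions, map genes into them, and perform hypergeometric gene-set
    enrichment with Bonferroni correction. A mosaic haplotype simulator
    with planted sweeps and planted term enrichment supports end-to-end
    validation without external genotype data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
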
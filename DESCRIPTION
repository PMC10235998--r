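Package: atacAllele
Title: Allele-Specific ATAC-seq Quantification at CRISPR-Edited Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual-locus allele-specific classification of ATAC-seq reads
    from CRISPR HDR-edited diploid clones, per-clone allelic ratios with
    exact binomial intervals, and an auditable statistical decision engine
    (normality and variance gates, log2 fallback, test selection,
    Holm-Sidak/Sidak/Dunnett adjustment). Includes a seeded paired-end
    read simulator with per-haplotype accessibility weights so the whole
    pipeline is testable against known ground truth, SAM text I/O with a
    mapping-quality filter, and an end-to-end reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
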
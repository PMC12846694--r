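Package: rohscan
Title: Runs of Homozygosity Detection and Inbreeding Analysis for SNP-Array Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in diploid SNP-array genotype
    panels with a PLINK-style sliding-window scan, and carries the analysis
    through to genomic inbreeding coefficients (FROH), ROH length-class
    summaries, per-population ROH islands (hotspot SNPs in the top tail of the
    ROH incidence spectrum), cross-population island sharing, and gene
    annotation of shared segments from a local GFF3/GTF file. Reads and writes
    PLINK PED/MAP and BED/BIM/FAM genotypes, applies standard marker and
    sample quality-control filters, and ships a multi-breed genotype simulator
    that implants autozygous tracts with recorded ground truth so that every
    stage of the pipeline can be validated without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
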
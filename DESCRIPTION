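Package: rohscan
Title: Runs-of-Homozygosity Detection, Inbreeding and ROH Islands from
    Dense Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in multi-sample diploid
    genotype data with a PLINK-style sliding-window scan, summarises them by
    length class and chromosome, estimates the genomic inbreeding coefficient
    F_ROH, locates ROH islands from per-SNP ROH incidence across individuals,
    and annotates islands with overlapping gene models.  Includes a synthetic
    diploid-genome generator that implants autozygous tracts of known location
    and total fraction, so the whole pipeline is testable against ground
    truth, plus a reproducible end-to-end pipeline driver with manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
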
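Package: radploidy
Title: Ploidy Inference for Polyploid Plants from Short-Read Allele Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the ploidy level of polyploid (notably diploidized
    allopolyploid) plant samples from the distribution of alternative-allele
    read fractions at biallelic sites, as observed in reduced-representation
    (RAD-seq) or whole-genome short-read data. Extracts per-site allelic
    depths from coordinate-sorted alignments or from VCF files carrying AD
    fields, applies coverage filters, estimates the allele-fraction density,
    and calls the effective copy number by matching density modes to the
    theoretical dosage fractions k/m, with a fixed-mean beta-mixture
    criterion as tie-breaker. Ships a read-depth simulator with known ground
    truth, an expected-ploidy calculus for admixed individuals (weighted
    arithmetic mean of lineage ploidies), neoploidy classification,
    nearest-class flow-cytometry genome-size classification, concordance
    summaries, and the polyploid inbreeding coefficient
    1 - H * ploidy / (ploidy - 1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
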
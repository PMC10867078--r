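Package: lcshkit
Title: Homozygosity, Consanguinity and Copy-Number Analysis for SNP
    Chromosomal Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of SNP chromosomal-microarray segment exports:
    selection of long contiguous stretches of homozygosity (LCSH/ROH) at a
    clinical >= 3 Mbp threshold with masking of hemizygous artifacts over
    deletions, estimation of the inbreeding coefficient F from summed
    autosomal LCSH with degree-of-kinship classification, rule-based calling
    of potential uniparental disomy (UPD) from single-chromosome homozygosity
    patterns, delineation of recurrent (common) LCSH regions across a cohort,
    copy-number-variant filtering and diagnostic-yield accounting, and
    phenotype-pathogenicity association. Includes a synthetic-cohort
    generator with known truth labels so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
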
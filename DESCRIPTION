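Package: proxburden
Title: Rare-Variant Gene Burden Testing Against External Controls with a
    Synonymous Proxy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based discovery of rare germline variant burden in small case
    cohorts tested against large external control panels. Implements composite
    variant quality control and rarity/deleteriousness filtering (population
    allele frequency, CADD, ClinVar, mapping quality, Hardy-Weinberg and
    allelic-fraction checks), a Poisson likelihood-ratio enrichment test that
    uses rare synonymous alleles as a proxy for case/control processing
    differences, genomic-control inflation correction, Benjamini-Hochberg
    false-discovery control, screening of candidate variants against external
    reference and tumor-series panels, exact clinical association tests, and a
    synthetic cohort generator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
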
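Package: mendelscope
Title: Mendelian Diagnosis of Congenital Skeletal Disorders from Ruminant
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-genome-sequencing based framework for diagnosing and
    classifying congenital skeletal disorders in cattle and sheep. Provides
    mode-of-inheritance driven variant filtering against pedigrees and control
    cohorts (homozygous recessive, compound heterozygous, dominant private and
    X-linked scenarios), de novo versus germline-mosaic discrimination from
    per-allele read depths, read-depth aneuploidy detection with
    parental-origin inference, identity-by-descent parentage verification,
    HGVS coordinate arithmetic, a machine-readable nosology catalog of
    ruminant skeletal disorders, and a seeded synthetic-data generator that
    emulates the cohort designs the framework targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
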
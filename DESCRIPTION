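Package: sdscan
Title: Sex-Determining Region Detection from Sexed-Cohort Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sex-linked genomic regions from whole-genome resequencing
    summaries of a sexed cohort and classifies the sex-determination system
    (XY versus ZW). Two complementary scans are combined: windowed read-depth
    contrasts between males and females (Welch two-sample t-tests on 1 kb bin
    means) and per-variant Fisher exact tests of genotype state (heterozygous
    versus homozygous) against sex. Candidate regions are merged, classified as
    XY-linked, ZW-linked, spurious or ambiguous from the joint depth and
    genotype evidence, and a cohort-level heterogamety verdict is returned.
    A synthetic-cohort simulator generates depth tables, VCFs and sample
    sheets with planted sex-determination architecture so the whole pipeline
    can be exercised and calibrated without access-restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
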
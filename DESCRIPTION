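Package: paleoPV
Title: Ancient-DNA-Aware Analysis of Pathogenic Variant Sharing Between
    Ancient and Modern Humans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing the evolutionary origin of pathogenic
    variants (PVs) in DNA damage repair (DDR) genes. Provides a
    damage-aware presence caller for ancient-DNA read evidence at known
    pathogenic-variant sites (terminal trimming, duplicate collapse,
    quality filters, C-to-T / G-to-A deamination handling), cohort-level
    sharing analysis between ancient and modern populations (Venn
    partitions, per-gene load comparison, temporal carrier profiles),
    rarefaction resampling to equalize cohort sizes, cross-species
    projection of human variants onto orthologous positions with clade
    summaries, bootstrap comparison of per-gene variant counts between
    selection classes, founder-variant age-table handling, and a seeded
    synthetic-data generator that emulates the statistical structure of
    the real inputs so the whole chain runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
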
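Package: chcohort
Title: Cohort-Aware Quality Control and Calling of Clonal Hematopoiesis
    Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns per-sample somatic variant calls (Mutect2-dialect VCF,
    optionally ANNOVAR-annotated) into cohort-level clonal hematopoiesis
    (CH) calls. Four tiers of quality filters are applied in order:
    cohort prevalence (allele and locus level), technical metrics (VAF,
    depth, alternate allele depth, per-strand support, strand odds ratio,
    TLOD), functional annotation (synonymity, repeat regions, germline
    database frequency with cancer-database rescue), and an optional
    paired-sample exact enrichment test against matched non-blood samples.
    A permutation procedure partitions the cohort into random disjoint
    subsets, re-runs the pipeline per subset, and measures call
    consistency against the full cohort across a grid of one tunable
    threshold, reporting the saturation (inflection) value as the
    cohort-specific cutoff. A seeded synthetic-cohort generator emulating
    whole-exome and ultra-deep sequencing regimes makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
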
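Package: lofburden
Title: Rare Loss-of-Function Variant Burden Analysis Against Reference
    Populations
Version: 1.0.0
Authors@R:
    person("Kit", "Lo", email = "kit.lo@example.org",
           role = c("aut", "cre"))
Description: Prioritization of rare loss-of-function (LOF) coding variants
    and domain-restricted burden testing for case-control cohort studies.
    Parses cDNA-level coding-change notation (both standard HGVS and the
    annotation-tool dialect), classifies consequences on a transcript model,
    maps affected residues onto protein domains such as the RAD50 zinc hook,
    aggregates carrier and allele counts across cohort strata, and compares
    carrier frequencies against frozen reference-population allele counts
    (gnomAD-style) with a two-sided Fisher exact test under the
    minimum-likelihood rule and the unconditional sample odds ratio. Includes
    a seedable synthetic-cohort generator for end-to-end testing and for
    characterizing type-I error and power of the exact test at realistic
    sample sizes, plus a command-line interface that renders reproduction
    reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
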
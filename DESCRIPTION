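Package: svscribe
Title: Haplotype-Aware Structural-Variant Discovery, Validation and
    Multi-Platform Integration
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for unifying structural-variant (SV) callsets across
    sequencing platforms with known-truth synthetic benchmarks.
    Implements Strand-seq inversion discovery from composite files of
    oriented reads (sliding-window read-ratio segmentation, exact
    three-model binomial genotyping, strand-aware haplotype-ratio
    classification and phasing), cross-platform inversion unification by
    reciprocal overlap and composite-file re-genotyping, multi-caller
    breakpoint consensus via empirical breakpoint confidence intervals
    and CI clustering, non-concordance-rate (NCR) analysis of caller
    combinations, long-read validation calculus (read-support, optical-map
    length concordance, read-depth), haplotype and assembly-level SV
    merging, and three-way pan-SV integration. A seeded synthetic-data
    module generates every input with planted truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    yaml
Config/testthat/edition: 3
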
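Package: recburden
Title: Recessive Genotype Burden Analysis for Trio and Singleton Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls biallelic damaging recessive genotypes (homozygotes,
    trio-phased compound heterozygotes, and panel-inferred compound
    heterozygotes in singletons) from annotated variant tables, stratifies
    cohorts by runs-of-homozygosity inbreeding coefficients, tests per-gene
    and gene-set burden against mutability-based expected counts with
    one-tailed binomial tests, estimates the fraction of probands
    attributable to recessive genotypes from parental depletion, computes
    founder-variant statistics (Hardy-Weinberg deviation with continuity
    correction, shared-haplotype extraction, allele-age estimation), and
    scores embryonic lineage specificity of candidate genes. Includes a
    synthetic cohort generator with planted ground truth for calibration
    and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
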
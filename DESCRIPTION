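Package: nf1mod
Title: Modifier-Gene Discovery for Quantitative NF1 Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a candidate modifier-gene
    discovery pipeline for quantitative neurofibromatosis type 1 (NF1)
    phenotypes such as cafe-au-lait macule (CALM) count. Provides an
    expression-phenotype regression screen with Benjamini-Hochberg FDR
    control and expression-level/range filtering, qPCR-style delta-delta-Ct
    verification, sequencing-based variant quality control (call-quality
    masking, missingness filters, monomorphic exclusion, exact
    Hardy-Weinberg testing, Mendelian trio checks), additive, dominant and
    rare-variant-collapsed genotype coding, covariate-adjusted
    single-variant regression, recombination-hotspot tiled stepwise
    regression, square-root-of-n weighted (Liptak/Stouffer) p-value
    meta-analysis, and pooled mega-analysis across cohorts. A synthetic
    cohort generator emulating the statistical structure of the study
    design (three cohorts, linkage-disequilibrium-correlated variants,
    planted genetic and covariate effects, partially trait-associated
    expression matrices) makes every stage testable end-to-end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
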
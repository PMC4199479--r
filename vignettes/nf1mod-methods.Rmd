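---
title: "Methods: modifier-gene discovery for quantitative NF1 phenotypes"
author: "nf1mod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modifier-gene discovery for quantitative NF1 phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nf1mod)
```

## The problem and the model

Neurofibromatosis type 1 is caused by heterozygous loss of the *NF1*
tumor suppressor, but its quantitative manifestations — the number of
café-au-lait macules (CALMs), neurofibroma burden, and similar traits —
vary widely between patients carrying comparable *NF1* lesions. The
working hypothesis of this pipeline is that germline variation in the
expression of *other* genes modifies that severity in an approximately
linear way. The package therefore chains two arms:

* an **expression arm** that regresses a quantitative phenotype on each
  transcript's abundance to nominate candidate modifier genes, and
* a **genotype arm** that sequences (in practice: receives genotypes
  for) candidate loci and tests variants for association with the
  trait, singly and jointly, within and across cohorts.

Throughout, the phenotype model is ordinary least squares on the count
trait `y` (optionally transformed as `log10(y + 10)`, which maps a
count of 0 to exactly 1 and tempers the right skew):

```
y = b0 + b_age * age + b_sex * sex + b_g * g + e
```

with sex coded female = 0, male = 1, and `g` one of three codings of a
variant: additive (minor-allele count 0/1/2), dominant (carrier 0/1),
or a collapsed rare-variant burden in [0, 1]. The genotype coefficient
is reported with its t-based two-sided p-value on the complete cases of
each fit.

## Expression screen

`preprocess_expression()` mirrors bead-array post-processing: subtract
a per-sample background offset, floor negatives to zero, quantile
normalize across samples, then take `log2(x + 1)`. Quantile
normalization is delegated to `limma::normalizeQuantiles(ties = TRUE)`
(rank means with average-rank tie handling); it preserves each sample's
rank order, which the tests assert. The screen regresses the phenotype
(response) on expression (predictor) — this orientation, rather than
the eQTL convention of expression-on-genotype, is deliberate and fixed:
the phenotype is the quantity being explained. Benjamini–Hochberg
adjustment (`bh_fdr()`, via `stats::p.adjust`) controls the FDR at the
deliberately permissive q < 0.3 — the screen feeds a verification
stage, so sensitivity is worth more than purity here. Candidates must
also show a mean log2 level of at least 6 and an expression range (max
− min) of at least 2; both exclusions are strict "below", so values
exactly at the threshold survive. A rescue list exempts transcripts
from the level/range filters (flagged `rescued`) but never from the FDR
filter: biological importance can excuse low or flat expression, not a
weak association. Verification re-runs the same regression on
qPCR-derived relative expression (`delta_delta_ct()`, fold change
2^−ΔΔCt) and keeps nominal p < 0.05.

## Variant QC

`run_variant_qc()` fixes the order of operations, which matters because
the filters interact: (1) mask calls with quality score below 99
(polyphred convention, strict "less than"); (2) drop samples with more
than 30% missing calls; (3) drop variants with more than 20% missing
calls *among the retained samples*; (4) drop monomorphic variants
(all-missing variants get their own reason code). Hardy–Weinberg
proportions are then tested with the exact conditional test — the sum
of probabilities of heterozygote counts no more probable than the one
observed, given the allele counts — on an unrelated subset formed by
keeping one member (lexicographically smallest id, for determinism) per
family, families being the connected components of the trio links.
Variants with exact p < 0.03 are flagged but retained: in a cohort
ascertained on disease, HWE departure can mark a causal variant as
easily as a genotyping artifact, so the flag is an annotation, never an
exclusion, and nothing downstream reweights on it. Mendelian trio
checks likewise annotate rather than filter. The exact test uses
log-gamma arithmetic with a 1 + 1e−12 relative tolerance when
comparing probabilities for the "no more probable" rule, so ties (e.g.
symmetric configurations) are counted into the tail rather than lost to
floating-point noise; the suite checks it against an independent
recurrence-based enumeration for every genotype table up to 200
alleles.

## Genotype coding and tiles

Rarity is classified on the analysis cohort after QC: MAF < 0.05 is
rare. Dosages are always expressed on the minor allele; readers fold
`2 − dosage` when the coded allele turns out to be the major one (ties
at 0.5 are left as coded). Tiles — the independence units of the tiled
regression — are derived from recombination-hotspot intervals: the
boundary between consecutive tiles sits at the *midpoint* of each
hotspot, so k hotspots yield k + 1 tiles that partition the chromosome
and a variant inside a hotspot still belongs to exactly one tile.
Hotspot BED input is 0-based half-open; variant positions are 1-based
(VCF convention); tiles are stored half-open. The collapsed coding for
the rare variants of a tile is, per sample, the proportion of the
tile's non-missing rare sites at which the sample carries at least one
minor allele; on a tile with a single rare variant this reduces exactly
to the dominant coding. The alternative reading — minor-allele count
over twice the non-missing sites — is available as
`method = "allele_fraction"`, with presence-proportion the default
because a "proportion of the minor allele at any site" reads most
naturally as a per-site carrier proportion.

## Tiled stepwise regression

The trait is residualized on age and sex once, up front
(`residualize_trait()`); the tile models then contain only genetic
terms. This differs intentionally from the single-variant analysis,
which carries the covariates inside each fit — pre-adjustment keeps the
stepwise search space small and makes every tile model comparable. Each
tile is screened by the overall F-test of the all-columns multiple
regression (retain if p < 0.2) or any single-column simple regression
p < 0.05; a tile with more columns than complete cases skips the F-test
and is screened on single columns only, with a logged notice. Within
retained tiles, `stepwise_select()` runs forward selection with
backward elimination: the candidate with the smallest partial p enters
if p < 0.05 (ties broken by the lower genomic coordinate, for
determinism), and after each entry any term whose p-value in the
refitted joint model reaches 0.05 is removed, worst first. Survivors
are pooled per chromosome and re-selected, then pooled genome-wide and
re-selected. Models are refit from scratch at every move rather than
updated incrementally — slower, but numerically transparent and easy to
cross-check against an independent executor, which the acceptance suite
does step by step. Collinear terms (a coefficient `lm` drops) are
treated as carrying no information: they are assigned p = 1 during
backward elimination, so one member of an aliased pair always leaves.

## Meta- and mega-analysis

`liptak_meta()` maps each cohort's p-value to a normal quantile
`z_i = Φ⁻¹(1 − p_i)` and combines with square-root-of-sample-size
weights, `Z = Σ √n_i z_i / √Σ n_i`, reporting `1 − Φ(Z)`. The mapping
deliberately ignores the sign of the cohort effect estimates. This is
the convention under which the published combined column is reproduced
— including the one SNP/model where the cohort betas disagree in sign —
and it amounts to combining evidence that each cohort's association is
extreme, with the two-sided p carrying the strength and the combination
assuming concordance. A signed variant (`signs =`,
`z_i = sign_i · Φ⁻¹(1 − p_i/2)`) is available for sensitivity analyses.
With one cohort the combination returns the input p exactly; with equal
sizes it reduces to unweighted Stouffer; p-values of exactly 0 or 1 are
rejected rather than silently saturated. `mega_analysis()` instead
pools individual-level data and adds cohort indicator variables to the
OLS design; a genotype collinear with the cohort labels yields a
reasoned missing result.

## The synthetic study generator

`simulate_study()` exists so that every stage is testable end to end
without access to individual-level data. Its defaults are the study
conditions, chosen once:

* **Cohorts** 89/29/62 with ages Normal(36.5, 13.8), Normal(38.1,
  12.7), Normal(15.2, 7.7) truncated at 1 year and male fractions
  0.39/0.45/0.56 — the published demographics of the three
  European-American analysis sets.
* **Variants** 118 on one chromosome (58 common, 60 rare with MAF
  5 × 10⁻³–2.5 × 10⁻², mean 0.015), interleaved along five
  hotspot-delimited tiles.
* **LD** one common pair at ρ = 0.9, emulating the rs7161/rs4660761
  tag-SNP pair. Haplotypes come from a Gaussian copula: thresholded
  standard normals whose latent correlation is solved numerically so
  the realized *allele-level* correlation hits the target. A target
  beyond the Fréchet bound for the two allele frequencies is rejected
  with an explanatory error. Notably, ρ = 0.9 is infeasible for
  frequencies 0.191 and 0.137 (bound 0.82) — sample correlations can
  exceed the population bound, population parameters cannot — so the
  default pair uses equal frequencies of 0.16.
* **Trait** latent Gaussian `12 + 0.05·age + 1·sex + Σβ·g + N(0, 8)`,
  rounded and floored at zero. One additive effect of −5 CALMs per
  minor allele is planted on one member of the LD pair, matching the
  magnitude of the discovery-cohort estimates. Counts are generated by
  rounding a Gaussian latent rather than by a Poisson/negative-binomial
  mechanism because the analysis model is ordinary linear regression;
  the generator matches the analysis assumption so that calibration
  properties (null uniformity of p-values) are exact rather than
  approximate.
* **Genotype observability** 2% of calls receive quality below 99 and
  1% are missing outright, so the QC stage always has work to do.
* **Expression** 1020 transcripts for the discovery cohort, 20 of them
  linearly trait-associated with |slope| in 0.03–0.08 log2 units per
  CALM and residual SD 0.5; null baselines span 5–10 and null residual
  SDs 0.1–1.0 so that the level-6 and range-2 filters both have
  material on either side.

What the generator does **not** emulate: realistic human LD maps or
haplotype block structure, population stratification, batch or array
effects in expression, genotyping error beyond quality-tagged
missingness, and any nonlinearity in the trait model. Green tests
therefore certify the statistical machinery under the model's own
assumptions; they are not evidence about robustness to model
misspecification in real data.

## Numerical choices and degenerate inputs

* Perfect-fit regressions report the smallest positive double rather
  than dividing by a zero standard error; zero-variance expression or
  constant genotypes yield flagged missing results with machine-
  readable reason codes, never exceptions.
* The stepwise loop carries a cycle guard (10 × the candidate count)
  although the entry/stay levels used here cannot cycle in practice.
* Exact HWE probabilities are computed from a single log-gamma pass and
  normalized in double precision; agreement with the independent
  recurrence oracle is ~1e−14 across all tables up to 200 alleles.
* Tile maps without a chromosome-length entry leave the last tile
  unbounded (`Inf`) rather than guessing an end.

## Problem sizes used by the test suite

The suite's simulation sizes were chosen as the smallest that make the
statistical assertions sharp: 100 replicates at n = 500 for
planted-effect recovery (observed recovery 100/100 against a ≥ 95
bound), 200 replicates of the 1020-transcript screen (observed mean
recall ≈ 0.997, pooled FDP ≈ 0.27 against a ≤ 0.3 + 3σ bound), ~2000
null fits for Kolmogorov–Smirnov uniformity, and exhaustive enumeration
for the exact-test and BH oracles. The whole default pipeline run
(three cohorts, 118 variants, both trait transforms) completes in a few
seconds.

## Known limitations

* The tiled procedure's selection p-values are post-selection
  quantities and are reported as such, without selective-inference
  correction — matching standard practice for this design, but they
  should be read as descriptive within the final model.
* The unsigned Liptak convention rewards consistently *extreme* cohort
  p-values even when effect directions disagree; the signed variant is
  the statistically conservative alternative and is one flag away.
* Gender-stratified screens are supported only by subsetting samples
  before the call; no stratified joint inference is implemented.
* The VCF reader covers the minimal biallelic unphased GT/GQ subset by
  design; multi-allelic records and phased data are out of scope.
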
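---
title: "Methods: recessive genotype burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive genotype burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recburden)
library(dplyr)
```

recburden implements the recessive arm of a large congenital heart disease
(CHD) exome study design: call biallelic damaging recessive genotypes (RGs)
in probands, stratify the cohort by consanguinity, test genes and gene sets
for RG burden against mutability-calibrated expectations, estimate how many
probands owe their disease to RGs, characterize founder variants, and score
candidate genes' embryonic lineage specificity. This vignette explains each
model, the tunable parameters, and the design decisions taken where the
underlying procedure was open to interpretation.

## Variant classification and filters

A variant is *LoF* when its consequence is stopgain, stoploss, frameshift
indel or a canonical splice change; *damaging missense* (D-mis) when
missense and predicted deleterious by MetaSVM **or** carrying CADD ≥ 30
(either score alone suffices — so a missense variant with MetaSVM missing
but CADD 35 is D-mis, and one with no scores at all is not damaging);
nonframeshift indels are damaging unconditionally. Synonymous variants form
the negative-control stream used to check calibration. *Rare* means allele
frequency < 10⁻³ in **both** reference panels; a missing frequency counts
as rare because absence from a large panel is itself evidence of rarity
(configurable via `missing_is_rare`).

The six-way genotype filter (GQ ≥ 20, DP ≥ 8, MQ ≥ 40, allele fraction
≥ 25%, ≥ 3 alternate reads, not in a segmental duplication) is applied only
in the contribution stage, where false-positive genotypes would inflate
in-cohort allele frequencies; gene-discovery RG calling runs unfiltered by
default, matching the two-stage design this package follows.

## RG calling

One RG is reported per sample–gene: a rare damaging homozygote, a
trio-phased compound heterozygote (at least one damaging allele inherited
from each parent; a site carried by both parents is phase-ambiguous and
conservatively excluded), or, in parentless probands, an inferred compound
heterozygote — a same-gene damaging pair never observed co-occurring in one
individual of a reference panel. When more than two alleles qualify, the
two most damaging are reported (LoF > D-mis > nonframeshift indel, ties by
lower population frequency then position); homozygotes take precedence over
compound heterozygotes in the same gene. The one-RG-per-gene rule prevents
combinatorial double counting when a gene harbours three or more qualifying
hets; the precedence order is a documented choice since the source design
does not state one.

## Consanguinity

F is estimated as the autozygous genome fraction from runs of homozygosity:
sliding windows of 50 consecutive markers with at most 2 heterozygous calls
are merged and runs shorter than 1.5 Mb discarded; F = total run length /
covered autosome length. This windowed estimator replaces haplotype-based
HBD phasing: it needs no external phasing step and preserves the contract
that F approximates the autozygous fraction, which is what the downstream
expectation model consumes. Window width, length floor and het tolerance
are exposed. A proband is consanguineous at F ≥ 0.0009, the fourth-cousin
expectation used operationally (the canonical fourth-cousin value is
2⁻¹⁰ ≈ 9.8 × 10⁻⁴; the 0.0009 cutoff is the one the analysis defines).
Default strata are ≥ 0.03, [0.0078, 0.03), [0.002, 0.0078),
[0.0009, 0.002) and < 0.0009 — approximations, configurable, since exact
stratum bounds are not published.

## Burden testing

Expected per-gene RG counts come from de novo mutability m via a
no-intercept degree-2 polynomial fitted to observed counts by nonnegative
least squares: `count ~ a·m + b·m²`. The mechanistic reading is that the
quadratic term carries random-mating biallelic events (two independent
alleles, each with frequency roughly proportional to mutability) while the
linear term carries autozygous events (one allele drawn homozygous by
descent), so the fitted mix adapts to the cohort's consanguinity level.
The degree is exposed because only "polynomial" is specified; the
two-parameter NNLS is solved exactly by active-set enumeration. Fitted
values are floored at 10⁻⁶ (flagged) so enrichments never divide by zero.
The fit uses all genes, tested ones included: a genome-wide fit is robust
to the sparse signal of a handful of true risk genes.

Genes and gene sets are tested with a one-tailed binomial,
p = P(X ≥ observed) for X ~ Binomial(n, expected/n); set expectations are
sums of gene expectations and are additive over disjoint sets. Bonferroni
significance uses 0.05/19,347 ≈ 2.6 × 10⁻⁶ by default; BH q-values are
also reported. Recurrence (genes with ≥ 2 RGs) is tested by dropping the
cohort's total RG count multinomially over genes with probabilities
proportional to expected counts; the empirical p uses the add-one
correction so it is never zero.

## Contribution estimation

The parental-depletion estimator reasons that parents of affected children
are depleted of damaging RGs causing severe early-onset disease while
probands are enriched, so the proband excess over a parent-calibrated
expectation, per proband, is the fraction of probands attributable to the
class:

$$\hat{c} = \frac{O_{pro} - E_{pro}\,O_{par}/E_{par}}{n_{probands}}.$$

Expectations use parental in-cohort allele frequencies (founder alleles,
avoiding proband enrichment bias) after carrier co-occurrence pruning:
of any same-gene pair co-occurring in more than half of the rarer member's
carriers, the rarer member is dropped — an internal substitute for
reference-panel LD pruning. For individual i and gene g the expected
biallelic probability is \((1-F_i)Q_g^2 + F_i Q_g\): two independent
damaging alleles under random mating, or one allele made homozygous by
descent. Parents are treated as outbred unless F values are supplied.

Observed biallelic events are counted **identically in parents and
probands**: a homozygous damaging genotype, or damaging alleles on both
haplotypes of phased genotypes. Phase-aware counting matters: the \(Q^2\)
model is a trans-pair probability, and counting any two same-gene hets
(cis pairs included) would double the baseline on both sides. The package
therefore consumes phased genotypes, emulating the statistical phasing
this kind of cohort receives upstream; with unphased input the counter
falls back to any-two-hets and says so. Symmetric counting is what keeps
the synonymous control centred at zero. Confidence intervals are
nonparametric percentile bootstrap over trios (B = 1,000 by default),
a documented choice since the original interval construction is not
specified in the main text. Stratified estimates recompute frequencies and
expectations within each stratum by default (`shared_frequencies = TRUE`
reuses whole-cohort statistics, making the whole-cohort estimate an exact
recombination of the strata); strata under 10 trios are flagged unstable.

## Founder statistics

Founder variants are summarized by: allele frequency from genotype counts;
Hardy–Weinberg deviation with a Yates-corrected 1-df χ², where the
corrected deviation is floored at zero so tables exactly at expectation
give χ² = 0 (continuity-correction conventions differ; this one is
deliberately conservative and verified to stay below the uncorrected
Pearson statistic); the predicted homozygote frequency q²; the maximal
interval around the focal variant over which all carrier chromosomes are
allelically identical; and a moment estimate of allele age. Each carrier
chromosome descends from the founder through g meioses, so its one-sided
shared length is Exp(g) per Morgan and the common interval's total length
is L ~ Gamma(2, m·g) for m carriers, giving ĝ = 2/(m·L) with an exact
pivotal CI from m·L·g ~ Gamma(2, 1). That interval is much wider than a
likelihood interval built from richer data would be; both the point and CI
methods are pluggable, and the pivotal CI is a stated substitute for the
original supplementary method. A uniform 1 cM/Mb map is the default;
a genetic map table overrides it.

## Lineage specificity

Expression profiles are normalized per gene by ratio-of-max; a gene is
lineage-specific when its top cell type is at least fivefold above **every**
other cell type (not just the second-highest — the stricter reading of
"compared to any other tissues"), which makes the rule scale-invariant per
gene and fail on ties. Genes are ordered by UPGMA (average-linkage)
clustering; the distance is Euclidean on normalized rows (the linkage, not
the metric, is specified; correlation distance is available). Specific gene
sets are then tested for RG enrichment on phenotype-restricted subcohorts
via the same binomial machinery.

## The synthetic cohort generator

The generator exists because the study's individual-level data are access
controlled; it reproduces the statistical structure the estimators assume,
with ground truth recorded. Defaults are the study conditions: 3,716 trios
and 1,708 singletons; 12.4% of probands consanguineous (spread over four
strata up to F = 1/16 — the published work gives only the consanguineous
share, so the within-share split is a modeling choice); per-gene damaging
allele-frequency mass Q_g proportional to log-normal mutability, with the
scale calibrated so an outbred proband expects 659.1/3716 ≈ 0.177 damaging
and 1951.5/3716 ≈ 0.525 synonymous biallelic genotypes — the cohort's
observed rates; every rare-pool allele frequency below 10⁻³.

Parental haplotypes are drawn from the allele frequencies; probands inherit
one haplotype per parent per gene, so two variants on one parental
haplotype co-transmit and genuine cis pairs occur. Autozygosity is
segmental: segments with mean length 20 Mb are placed so the autozygous
genome fraction equals each proband's F, genes inside a segment become
homozygous by descent, and both parents are set to carry the shared allele,
keeping Mendelian consistency. Causal genes default to the 25 genes nearest
the median damaging-frequency mass — causal recessive disease genes are
ordinary genes, and planting in the most polymorphic genes would distort
the parental calibration the estimator relies on. A configurable fraction
of probands receives a planted homozygous or compound-heterozygous RG with
obligate-carrier parents. QC fields default to passing values; `qc_noise`
injects failures. Marker genotypes for ROH estimation are generated
separately (`simulate_marker_genotypes`) so rare-variant cohorts do not pay
the dense-marker cost.

What the generator does **not** emulate: linkage disequilibrium beyond the
founder haplotype, sequencing-level artefacts, population stratification,
X-linked inheritance, and relatedness between families. Passing calibration
and recovery tests on these cohorts therefore demonstrates correctness of
the estimators under the stated model, not robustness to every property of
real exome data.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use cohorts of 2,000–5,000 trios
with 300–400 genes (50 replicates for parameter recovery, 20 null cohorts
for calibration, 500 founder replicates, 100 individuals for the
F-estimator check at 10⁴ markers) — sizes chosen so each property is
measured with useful precision while the whole suite stays quick to run.
The gene count only sets the background event rate (the allele-frequency
calibration is gene-count invariant), so estimator behaviour does not
depend on it. Fitted expected counts are floored at 10⁻⁶; bootstrap and
permutation p-values use add-one corrections; NNLS columns are rescaled to
unit norm before solving to keep the monomial basis well conditioned;
ties in damage ranking break by population frequency then position so all
calls are order-independent and reproducible under a fixed seed.

## Known limitations

Singleton compound-heterozygote inference cannot see phase, so cis pairs
absent from the co-occurrence panel are called at roughly twice the
trio-phased rate — as in any panel-absence method; rate tables therefore
separate `comphet` from `inferred_comphet`. The allele-age moment estimator
is median-biased upward by construction (the reciprocal of a Gamma(2)
variable); at the scales tested the marker-level haplotype detection
offsets most of this. The windowed ROH estimator slightly underestimates F
when segments fall below the window's span and slightly overestimates at
run edges; at first-cousin F both effects are small and partially cancel.
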
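---
title: "strpanel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strpanel: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strpanel` builds phased SNP+STR reference panels from quad-family
cohorts, imputes STR genotypes into SNP haplotypes, and quantifies how
well that works. This vignette is the package's account of the science:
the models it assumes, the parameters that matter, the choices made where
the design was genuinely open, and what its synthetic cohorts can and
cannot establish.

## The problem

Short tandem repeats mutate by gaining or losing whole motif copies at
rates orders of magnitude above SNPs. A new length allele arises on a
particular SNP haplotype background and initially travels with it;
recombination and recurrent mutation then erode that association. SNP-STR
linkage disequilibrium (LD) is therefore real but much weaker than
SNP-SNP LD, and imputation of STR lengths from SNP haplotypes is
possible but imperfect — the whole pipeline exists to measure and exploit
exactly that partial signal.

## The synthetic cohort generator

`simulate_founder_haplotypes()` produces haplotypes by sequential
copy-with-mutation rather than a coalescent: a small set of seed
haplotypes receives independent Bernoulli(0.5) SNP alleles, and each
subsequent haplotype copies a uniformly chosen earlier one with

* per-site template switching (`recomb_switch_rate`), the knob that
  erodes SNP-STR LD;
* per-site SNP mutation (`snp_mutation_rate`);
* stepwise STR mutation (`str_mutation_rate`): step size of $k \ge 1$
  repeat units with $k - 1 \sim \mathrm{Geometric}(p)$
  (`str_step_geom_p`), sign $\pm$ with equal probability.

This was chosen over a coalescent simulator because LD strength is then
directly and monotonically tunable (template switching is the only force
decoupling the STR from its background when mutation is disabled), the
generator is a few dozen lines auditable in one sitting, and no external
simulator is required. STR alleles are stored everywhere as signed bp
offsets from a declared reference length; mutation and stutter act in
repeat units and are converted through the motif period immediately, so
a single unit system flows through panels, VCF export and dosages.

Seed haplotypes treat their STR allele like a copy of the reference:
a mutation event occurs with the same per-copy probability, so
`str_mutation_rate = 0` leaves the locus monomorphic. For constructions
that need a prescribed allele configuration (e.g. two seed backgrounds
with distinct alleles in perfect LD), `seed_str_alleles` pins the seed
offsets explicitly.

`simulate_quads()` draws two panel haplotypes per parent (with
replacement) and recombines each parent's pair per meiosis. Genotyping
errors are layered on separately by `inject_genotyping_errors()`:
symmetric ±1-repeat-unit PCR stutter per called allele (`stutter_up`,
`stutter_down`) and genotype-level dropout (`dropout_rate`), matching
how call rate is defined downstream. Multi-unit stutter and allele-biased
dropout are deliberately out of scope.

Default rates (SNP mutation 0.002/site, switching 0.002/site, STR
mutation 0.05/copy, stutter 0.01 up / 0.02 down, dropout 0.02) were fixed
once as a moderate-LD, low-error regime in which a multi-allelic STR
segregates on partially informative backgrounds — polymorphic enough to
make imputation non-trivial, clean enough that Mendelian rates sit near 1.
No real stutter rates are estimated anywhere; they are free parameters of
the generator, not inferences.

What the generator does **not** emulate: read-level evidence (quality
scores, flank indels), realistic human recombination maps, sequence-level
(non-length) STR variation, population structure, and the genome-wide
scale of real panels. Passing tests therefore establish the correctness
and calibration of the statistical machinery under the assumed generating
process — not the absolute imputation accuracy achievable on any real
cohort.

## Quality control

Five locus filters are applied by `apply_locus_filters()`: segmental
duplication overlap (≥1 bp against a BED file; BED is 0-based half-open,
all internal coordinates are 1-based inclusive, and the conversion lives
in one place), homopolymer-containing penta-/hexanucleotides (run ≥5
resp. ≥6 in motif or reference sequence), call rate < 80%, expected
heterozygosity < 0.095 (strictly below: a bi-allelic locus at exactly 5%
minor allele frequency, H = 0.095, survives), and Hardy-Weinberg
departure at p < 0.01.

The HWE statistic was an open choice. The package tests the heterozygote
*count* against Binomial(n, H) with an exact two-sided p-value
(minimum-likelihood two-siding, identical to `binom.test`), rather than a
genotype-table chi-square: with many STR alleles most genotype cells are
near-empty and the chi-square approximation degrades, while heterozygote
excess/deficit remains well defined for any allele count. A monomorphic
locus is defined to have p = 1. Call rate uses all cohort samples in the
denominator. Mendelian consistency uses length alleles only — a child
call is consistent if one allele can be drawn from each parent's pair —
and families homozygous reference in all four members are excluded from
the denominator, since such families are uninformative and would inflate
the rate; with no countable child calls the rate is undefined (`NA`),
never 0.

## LD metrics

Dosage is the sum of the two allele offsets. Length *r*² is the squared
Pearson correlation of dosage vectors, computed after pairwise-complete
deletion (the convention adopted for all r² computations; missingness is
genotype-level so this is the natural choice). Zero variance yields `NA`,
never 0 — an undefined correlation is not evidence of no correlation.
Allelic *r*² correlates per-sample copy counts (0/1/2) of one allele
between truth and imputation; cohort-level reports restrict it to common
alleles (frequency ≥ 5%). For a bi-allelic locus the two definitions
coincide algebraically, which the test suite asserts to 1e-12.

`best_tag_snp()` searches ±50 kb (configurable) anchored at the STR
*start* coordinate — the start is always defined, whereas a midpoint
shifts with the reference allele length — codes SNPs as minor-allele
counts (r² is invariant to the coding; only reported signs change), and
breaks ties by smaller distance, then lower position, making the choice
deterministic.

## Phasing, panel construction, imputation

`phase_quads_by_transmission()` resolves parental phase from inheritance:
haplotype 1 of each parent is *defined* as the allele transmitted to
child 1. A site resolves directly when the transmitted allele is unique
given the mate's genotype; sites where both parents and the child are
identically heterozygous are phased by linkage with the nearest
transmission-resolved heterozygous site, using child 2's inherited
haplotype index there as the anchor; residual ties take the smaller
allele first. Mendelian-inconsistent sites (checked against both
children, whatever the parental zygosity) are set missing for the whole
family and counted. Because haplotype 1 tracks the transmitted allele,
a meiotic recombination event makes the reconstructed haplotype chimeric
with respect to the parent's physical chromosomes; at the within-window
scale the package targets (tens of kb) this is rare and harmless for
imputation, and accuracy is asserted against the simulator's recorded
transmitted haplotypes.

`build_reference_panel()` stacks the parents' phased haplotypes
(children are excluded — they duplicate parental material). Missing STR
alleles are filled with the most frequent allele among haplotypes sharing
the longest exact SNP match, matching nearest SNPs first since LD decays
with distance; missing SNP alleles take the site's major allele, so every
panel column is fully resolved by construction.

`impute_str()` replaces an HMM-based imputer with a deterministic
weighted-mismatch matcher: panel haplotypes are scored by
$\sum_j w_j \, [x_j \ne h_j]$ over window SNPs with
$w_j = 1/(1 + d_j/\text{kb})$, and the STR allele of the minimum-score
haplotype is copied. The weighting privileges SNPs near the STR,
approximating LD decay with distance. Ties go to the most frequent STR
allele among tied haplotypes, then the smallest — frequency is the best
prior under ambiguity, and the final tie-break makes results independent
of panel row order (a property the tests check by removing and re-adding
a sample). Imputation is haploid, per target haplotype; unphased targets
are out of scope. A Li-Stephens HMM with explicit recombination and
mutation parameters, and genotype-likelihood-aware matching, are known
limitations; the panel VCF export keeps the door open to external
imputers.

## Evaluation and null models

Concordance scores an imputed against a true unordered genotype under a
one-to-one matching: 1 if both alleles match, 0.5 if exactly one can be
matched, 0 otherwise — so (10,10) vs (10,12) scores 0.5, not 1: the
second imputed 10 has no partner. Samples whose observed or imputed
genotype carries an allele seen fewer than 3 times in the cohort's
observed calls are excluded from all evaluation metrics; an imputed
allele never observed at all has count 0 and is excluded by the same
rule.

Two null imputers calibrate expectations. The *random* model draws both
alleles independently from cohort frequencies; its expected concordance
is computed exactly by summing over genotype pairs weighted by their
Hardy-Weinberg probabilities (at $f = \{0.5, 0.5\}$ this gives 0.625),
and its r² values by one seeded random genotype per sample — one draw,
not an average over many, so the null carries the same sampling noise as
a single real imputation run. The *naive* model always imputes the
empirically most frequent diploid genotype (ties: smaller dosage, then
lexicographic), under which r² is undefined. A locus is stratified as
multi-allelic when it has ≥3 common (≥5%) alleles.

## Association, power, eSTR

Trait simulation standardises the dosage to mean 0 and *population*
variance 1 (divisor $n$). The additive model is
$P = \beta G + E$ with $E \sim N(0, 1-\beta)$, reading $1-\beta$ as the
noise **variance**; the alternative reading (standard deviation) would
change the implied effect/noise trade-off but not the calibration
structure, and the variance reading keeps $\beta = 1$ exactly noiseless.
$\beta > 1$ is rejected. The case-control model draws Bernoulli outcomes
with $\mathrm{logit}(p_i) = \beta X_i$. The quadratic model forms
$G_q = d_i^2 / \overline{\ell}$ — squared dosage divided by the cohort
mean *absolute* allele length (reference length plus offset), which keeps
the divisor positive where raw offsets average near zero — then
standardises $G_q$ so the same noise convention applies.

Power is the fraction of seeded simulations with nominal $p < 0.05$,
100 simulations by default, reported per tested encoding (causal STR,
imputed STR, best tag SNP). The default cohort size for power work is 950
(the parents of a 479-quad cohort minus a small loss to missingness).
Logistic fits flag likely separation (non-convergence or runaway
estimates) rather than reporting a spurious p-value.

The eSTR scan drops genes with median expression 0, quantile-normalises
expression to a standard normal using the $(r-0.5)/n$ plotting position
with average ranks for ties, standardises STR dosage, and fits a linear
model with user-supplied covariates (principal components, PEER factors
and the like are consumed as a numeric matrix; estimating them is out of
scope). The nested comparison `Y ~ eSNP` vs `Y ~ eSNP + eSTR` is a
one-degree F-test; an eSTR collinear with the eSNP is flagged undefined.
The default eSTR cohort size is 336, the scale of a single-tissue
expression panel. In the generative counterpart used for testing
(`simulate_expression()`), the covariate is a centred binary sex
indicator with effect 0.2: large enough to matter in the fit, small
enough that total expression variance stays near 1, so quantile
normalisation is close to an identity on the scale of $Y$ and slope
recovery can be assessed against the simulated $\beta$ without a
scale correction.

## Founder haplotype analysis

Pathogenic repeat expansions typically arise once, on a specific SNP
background; haplotypes near that background should carry longer repeats.
`hamming_to_founder()` counts mismatches to a declared founder haplotype
(the nine-marker DRPLA/ATN1 definition ships with the package) with
strict rejection of haplotypes missing a founder marker — silently
imputing a missing marker would bias distances downward. Distances are
computed on phased haplotypes only. `length_distance_correlation()`
reports the Pearson correlation of repeat length with distance and
per-distance length summaries.

`simulate_founder_drift()` provides the generative counterpart: each
haplotype has an age $u \sim U(0,1)$, accumulates
$\mathrm{Poisson}(4u)$ marker mismatches (capped at 9) and contracts by
$\mathrm{Poisson}(6u)$ repeat units from an expanded founder length of
20 units. The rates were fixed once as a plausible drift scale producing
distances spanning the full range at $n$ of a few hundred; the package
asserts only the *sign* and significance of the resulting correlation,
not its magnitude.

## Numerical choices and degenerate inputs

* All r² undefined cases (zero variance, <2 complete pairs) return `NA`
  and are excluded from means, never coerced to 0.
* Exact binomial two-siding uses the minimum-likelihood rule with a
  `1 + 1e-7` likelihood slack, as in `binom.test`.
* Score ties in imputation use a `1e-9` slack on the weighted mismatch
  to absorb floating-point noise in the weights.
* Every stochastic step takes an explicit seed; identical seeds give
  bit-identical outputs, which the suite asserts for the generator, the
  random null, and the imputer.

## Problem sizes

Tests and the acceptance script run at desk scale, chosen once: regions
of 40 SNPs + 1 STR, panels of 120–240 haplotypes, 30–60 quad families
(479 only where the quad-design arithmetic itself is asserted), 950
samples for power, 336 for eSTR, 1000 replicates for the two calibration
rates (type-I error, HWE firing), 100 for coverage and power curves, and
10 replicates per point on the LD grid. These sizes make Monte-Carlo
tolerances (3 SE bands, binomial confidence intervals) wide enough to be
stable across seeds while keeping the full suite in the minutes range.

## Known limitations

No read-level error model; no recombination maps; haploid-target
imputation only; no Li-Stephens HMM; no population stratification in
evaluation (sample lists are supported structurally, but no ancestry is
computed); nominal p-values throughout, with multiple-testing policy left
to the caller; and synthetic cohorts whose LD structure, while tunable,
is simpler than real human haplotype diversity.
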
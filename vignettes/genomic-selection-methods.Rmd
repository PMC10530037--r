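---
title: "Genomic prediction of salinity tolerance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of salinity tolerance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltgp)
```

## Scope

`saltgp` implements a genomic-selection workflow for panels of inbred rice
lines evaluated under two hydroponic conditions (control and mild salinity
stress): marker quality control and redundancy pruning, genomic kernels,
Bayesian single- and multi-environment prediction, CV1 cross-validation of
predictive ability, stress-response indices, and the selection of a
representative validation subset from a breeding population. A
synthetic-data generator with known truth makes the whole chain testable
end to end without any external data.

## Marker quality control

Markers are discarded when their call rate falls below 75%, their
heterozygosity rate exceeds 10%, or their minor allele frequency falls
below 5% (defaults of `filter_thresholds()`). Rice accessions at this
stage are fixed lines, so heterozygous calls are treated as genotyping
artifacts: surviving heterozygotes are converted to missing, and the
missing rate recorded at that point is kept as the pre-imputation missing
rate used later as a pruning tie-break. Two deliberate details:

* A marker failing several criteria is attributed to the first failing
  criterion in the order call rate, heterozygosity, MAF — an arbitrary but
  fixed order that makes filter reports reproducible.
* MAF is computed on homozygous calls only. Heterozygotes are blanked
  before any downstream use, so including them would let a marker pass on
  calls that are about to be removed; computing MAF on the calls that
  remain also makes the filter idempotent. A borderline marker whose call
  rate only just clears the threshold before het conversion can still, in
  principle, fall below it afterwards; with realistic call rates
  (> 90%) and het rates (< 10%) this boundary case does not arise.

Missing calls are then filled per marker with the modal (or rounded-mean)
dosage — deliberately naive plumbing so kernels have complete data;
haplotype-based imputation is out of scope and should be run externally
when real panels are analyzed.

Markers in complete linkage disequilibrium (pairwise r² = 1 on the imputed
dosages) are pruned to one representative per cluster, chosen by lowest
pre-imputation missing rate, then highest MAF, then map position.
Redundancy is detected by a canonical column signature (standardized,
sign-fixed, rounded to 9 decimals), which captures every |r| = 1 affine
relation between integer dosage columns — not only the dosage ↔ 2−dosage
flip — in O(np) time; zero-variance columns are left as singletons since
correlation is undefined for them.

## Kernels and the RKHS bandwidth

The linear (GBLUP) kernel is K = XX′/p on the column-centered dosage
matrix X with p markers; the Gaussian (RKHS) kernel is
K(xᵢ, xⱼ) = exp(−h‖xᵢ − xⱼ‖²) on the raw dosages (distances are invariant
to column centering, which the tests assert). Squared distances are not
normalized by their mean; a practitioner can rescale h instead, and the
bandwidth estimator works on whatever scale the distances have.

The bandwidth h is estimated by the mode of the joint posterior of h and
the residual-to-genetic variance ratio φ under the one-kernel model
y = 1μ + u + ε, u ~ N(0, σ²ᵤ K_h), ε ~ N(0, φσ²ᵤ I): μ is integrated
under a flat prior and σ²ᵤ under a conjugate scaled-inverse-χ² prior
(5 degrees of freedom, scale set from the phenotypic variance), giving a
closed-form marginal likelihood per grid point via one eigendecomposition
of K_h. The prior on h is Gamma(shape 3.0, scale 1.5), whose mode is 3.0;
the prior on φ is flat on log φ over [10⁻³, 10³], a weakly informative,
scale-free choice. The search grid is 50 log-spaced h values spanning
[10⁻⁴, 10²]/median(d²), widened to cover the gamma prior's central mass,
and the grid argmax is refined by a bounded 1-D optimization between its
neighboring grid points. On data with no genetic signal the likelihood is
flat in h and the estimate reverts to the prior mode — a behavior the
acceptance suite checks.

## Phenotype modeling

The split-plot analysis fits, per trait, value ~ condition × genotype with
random replicate and tank-within-replicate intercepts by REML (`lme4`),
falling back to ordinary least squares when the mixed fit fails. The
genotype × condition interaction is included even though per-condition
means are wanted mainly for main effects: without it, per-condition
adjusted means are not estimable. Adjusted means are fixed-effect
predictions per genotype × condition cell with random effects set to zero;
on balanced complete data they equal raw cell means, which the tests use
as an oracle identity. For small designs (such as a 41-line validation
experiment) the two random terms can be combined into a single tank term
(`random = "combined"`).

Stress-response indices are iTRAIT = (salt − control) × 100 / control on
adjusted means, undefined (and logged) when the control mean is zero.
Genotype-by-condition interaction strength is summarized by the rank
correlation of adjusted means between conditions; Spearman is the default
and Kendall an option, since both conventions are in circulation.
Repeatability uses the genotype-mean formula H² = σ²_g/(σ²_g + σ²_ε/r̄)
with r̄ the harmonic-mean replicate count — the standard plant-breeding
definition; the package treats a zero genotype variance as H² = 0.

## The Gibbs samplers

The single-environment model is y = 1μ + u + ε with u ~ N(0, σ²ᵤK) and
ε ~ N(0, σ²ₑI). The multi-environment (here: multi-condition) model stacks
environments and splits the genetic signal into a main effect u₀ shared
across environments (covariance σ²ᵤ₀K₀) and environment-specific effects
u_j (covariance σ²ᵤⱼK_j), with per-environment intercepts and, by default,
per-environment residual variances (a pooled-residual option exists).
Both are fitted by one Gibbs core:

* Genetic effects are sampled in the eigenbasis of their kernel
  (eigenvalues below 10⁻¹⁰ dropped), where the full conditionals are
  independent normals — O(n) per update plus one matrix-vector product.
  Eigendecompositions are computed once per kernel and reused across
  cross-validation replicates.
* Variance components have scaled-inverse-χ² full conditionals with
  df₀ = 5 and scales chosen so the prior mode allocates R² = 0.5 of the
  phenotypic variance to the genetic side (split evenly between main and
  specific components in the multi-environment model) — the common
  Bayesian-GBLUP default when no stronger prior information exists.
  Intercepts are flat-prior normals.
* Missing phenotypes (masked validation lines, lines unobserved in an
  environment, an unphenotyped breeding population) are handled by data
  augmentation: they are redrawn from the current model each iteration,
  contribute no information, and receive predictions through the kernel
  covariance. This keeps the eigenbasis updates exact under any missing
  pattern.

Defaults are 35,000 iterations, 5,000 burn-in, thinning 10 (3,000 retained
draws); convergence is checked with the split-chain Gelman–Rubin PSRF on
two or more chains seeded consecutively from the master seed. Tests and
cross-validation use shorter chains (800–22,000 iterations depending on
what is being measured); the posterior means they consume stabilize well
before the defaults, and the oracle checks quantify the Monte-Carlo error
explicitly via batch means.

At fixed variance components the posterior mean of the genetic effects
equals the closed-form BLUP K V⁻¹(y − μ̂) with V = σ²ᵤK + σ²ₑI and μ̂ the
GLS intercept — the package's central correctness oracle, checked for both
kernel types and for masked-line prediction. Since the check compares ~50
coordinates simultaneously at 3 Monte-Carlo standard errors each, the
tests allow the expected number of chance exceedances instead of requiring
a simultaneous 3σ bound, which would fail spuriously about one run in
eight.

One design consequence worth naming: `fit_single_env` is the m = 1,
no-specific-effect case of the same core, so the nested-model reduction
(multi-environment → single-environment) holds by construction and is
asserted draw-for-draw under a shared seed. The complementary limit — the
environment-specific variances pinned near zero with a second, fully
masked environment — is checked against the single-environment fit within
Monte-Carlo error.

## Cross-validation and its analysis

CV1 partitions assign 80% of lines (floor(0.8·n)) to training and the rest
to validation, repeated 100 times by default, and the same partitions are
reused across every trait × method × model cell so comparisons are paired.
Validation lines are masked in all environments before fitting; predictive
ability is the Pearson correlation between their predictions and observed
adjusted means, per condition. Replicates where the correlation is
undefined (zero variance) are recorded as missing and excluded from cell
means with their count reported, rather than imputed as zero.

Predictive abilities are compared on the Fisher-Z scale
Z = 0.5 ln[(1+r)/(1−r)] by a fixed-effects type-II ANOVA on the design
factors, with the partition index as a blocking factor — the partitions
are shared, so the block captures their common variation. A degenerate
all-equal-Z table yields an all-zero ANOVA rather than an error.

One property of CV under the null is worth knowing when reading test
output: conditional on a single phenotype vector of pure noise, mean
predictive ability over partitions is not centered at zero — the noise
vector's chance alignment with the kernel's population-structure axes
biases every partition the same way. The null test therefore averages over
fresh noise draws.

## Breeding-population prediction and subset selection

Prediction of an unphenotyped breeding population builds one kernel over
the union of reference and breeding lines restricted to their common
markers (refusing to run below 50% marker overlap), masks the breeding
population, and fits as usual. Predictions shrink toward the reference
mean, more strongly for RKHS than GBLUP.

The validation subset (41 lines by default, sized to fit a replicated
hydroponic experiment) is chosen to span the predicted variability of the
key salt-tolerance traits (Na, K, Na/K, iSHOOT, iROOT by default) under
both prediction methods. How multiple traits and methods combine into one
ranking is genuinely open; the package uses the simplest deterministic
reading: each line's consensus score is its mean percentile rank across
trait × method cells, lines below the 0.10 consensus quantile form the
bottom stratum and above 0.90 the top, and quotas are floor(0.20·n_sel)
bottom, floor(0.20·n_sel) top, remainder middle (8/8/25 at 41). Within a
stratum, lines are taken at evenly spaced quantiles of the consensus score
— a maximum-spread rule chosen over random draws for reproducibility —
with ties broken by line identifier. Selection depends only on ranks, so
it is invariant to any monotone transform of the predictions, and a
stratum smaller than its quota donates the deficit to the middle stratum
with a warning.

## Population structure

Dissimilarity between lines is simple matching (the fraction of markers
with unequal calls, a heterozygous call mismatching both homozygotes),
computed via indicator cross-products so panel-sized matrices are
practical. Trees are Saitou–Nei neighbor joining with negative branch
lengths clamped to zero, written as newick. Group assignment runs PCA on
centered dosages, keeps the fewest components explaining 90% of variance,
and k-means with seeded restarts (k = 3 separates temperate japonica,
tropical japonica and admixed material). The discriminant step of a full
DAPC is omitted: downstream use needs group labels only, and the
clustering step of DAPC is itself PCA + k-means. Published admixture
percentages from full DAPC are therefore not reproduction targets.

## The synthetic generator

`simulate_genotypes()` draws a Balding–Nichols panel: ancestral allele
frequencies uniform on [0.1, 0.9], two subpopulations with
Beta(p(1−F)/F, (1−p)(1−F)/F) frequencies (F = 0.1 by default), and a 37%
admixed fraction whose per-locus ancestry follows an individual admixture
coefficient uniform on (0, 1). Lines are fully inbred (dosage 0/2),
matching fixed-line panels; heterozygotes and missing calls are injected
only as QC test material. Defaults (600 individuals, 17,000 markers on 12
chromosomes) emulate the scale of a reference panel plus breeding
population; tests and the acceptance script pass smaller explicit sizes
(30–400 individuals, 100–3,000 markers) chosen so each property is
measurable in seconds to a couple of minutes.

`simulate_effects_and_phenotypes()` splits causal effects into a shared
component β₀ and condition-specific components β_j with
σ²₀/(σ²₀ + σ²_E) equal to the target genetic correlation ρ_G, builds
genetic values on raw centered dosage columns (consistent with K = XX′/p,
so the simulated genetic covariance is proportional to the kernel),
standardizes them to the target per-condition heritability, and generates
split-plot observations (3 replicates, 6 tanks per condition, replicate
and tank variance fractions 0.15/0.10 of the non-genetic variance).
Default trait settings place heritabilities in 0.50–0.85 and genetic
correlations in 0.30–0.80 — inside the repeatability (0.44–0.93) and
rank-correlation (0.25–0.83) ranges such two-condition salinity panels
display — with Na and K generated under salt only, as ion mass fractions
are measured only there.

What the generator does not emulate: linkage between markers within a
chromosome (markers are independent, so LD-decay-based analyses are out of
reach), selection or pedigree structure, genotype-dependent measurement
error, and trait-trait genetic correlations. Passing tests therefore
demonstrate the machinery's correctness under the stated generative model,
not calibrated performance on real panels.

## Numerical choices and degenerate inputs

* Kernel PSD checks tolerate eigenvalues down to −10⁻⁸ · trace/n;
  eigenvalues below 10⁻¹⁰ are excluded from genetic-effect bases.
* Redundancy detection rounds standardized columns to 9 decimals —
  exact for integer dosages by a large margin.
* A constant dosage column centers to zero, contributes nothing to the
  kernel, and forms its own pruning singleton.
* An all-missing marker is an error naming the marker; an empty filter
  result is an explicit error; `fisher_z(±1)` is an error unless clamping
  is requested explicitly.
* Repeatability returns 0 when the genotype variance estimate is 0; a
  single-genotype phenotype table degrades the fixed part to
  value ~ condition.
* All stochastic components (generator, partitions, samplers, k-means
  restarts) run from explicit seeds; chains and CV replicates derive
  per-unit seeds from the master seed so reruns are bit-identical.

## Known limitations

Beyond the generator simplifications above: the naive imputer is not a
substitute for haplotype-based imputation on real data; marker-effect
models (Bayes A/B/Cπ, Bayesian LASSO) and GWAS-weighted kernels are out of
scope; CV2/sparse-testing designs are not implemented; and the bandwidth
estimator fixes one defensible integration scheme (flat μ, conjugate σ²ᵤ,
flat log φ) among several published variants — its internal grid-argmax
oracle, not any external implementation, defines its correctness.
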
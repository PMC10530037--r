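# saltgp

Genomic selection for salinity tolerance in temperate *japonica* rice —
a tested, reusable R implementation of the full analysis chain:

* **Marker QC**: call-rate / heterozygosity / MAF filters,
  heterozygote-to-missing conversion, naive imputation, and pruning of
  markers in complete linkage disequilibrium (r² = 1) with the
  lowest-missing / highest-MAF representative rule.
* **Genomic kernels**: linear GBLUP kernel K = XX′/p on centered dosages,
  Gaussian RKHS kernel exp(−h‖xᵢ−xⱼ‖²), and posterior-mode estimation of
  the bandwidth h under a Gamma(3.0, 1.5) prior.
* **Bayesian prediction**: bespoke Gibbs samplers for the
  single-environment model y = 1μ + u + ε, u ~ N(0, σ²ᵤK), and the
  multi-environment model y = μ + u₀ + u_E + ε with a shared main genetic
  effect and condition-specific effects; masked lines are predicted
  through the kernel covariance; split-chain Gelman–Rubin diagnostics.
* **Evaluation**: CV1 cross-validation (80/20, 100 shared partitions),
  predictive ability as the Pearson correlation between predictions and
  adjusted means, Fisher-Z transformation Z = ½ln[(1+r)/(1−r)] and ANOVA
  on Z, method-agreement correlations.
* **Phenotypes**: derived traits (LA = LGTH × WDTH × 0.75, SLA, R/S,
  Na/K), split-plot mixed model for adjusted genotype means, stress
  indices iTRAIT = (salt − control) × 100/control, repeatability,
  genotype-by-condition rank correlations.
* **Selection**: train on a reference panel, predict a breeding
  population, and pick a representative validation subset (bottom decile /
  top decile / average lines in 20/20/60 proportion; 8/8/25 at the default
  41 lines).
* **Structure**: simple-matching dissimilarity, unweighted neighbor-joining
  tree (newick), PCA + k-means group assignment.
* **Synthetic data**: a Balding–Nichols generator (two subgroups plus
  admixture, inbred lines, split-plot phenotypes with known heritability
  and cross-condition genetic correlation) so every claim above is tested
  against known truth.

Who it is for: quantitative geneticists and rice breeders who want to
evaluate or run genomic prediction with genotype-by-condition structure,
and anyone needing a transparent, oracle-tested reference implementation
of kernel-based Bayesian genomic prediction.

## Worked example

Simulate a structured panel, run QC, fit the multi-environment GBLUP model
under cross-validation:

```r
library(saltgp)

sc  <- sim_config(n_individuals = 150, n_markers = 1200, seed = 42)
sim <- simulate_genotypes(sc, inject_qc_noise = TRUE)
qc  <- filter_markers(sim$genotypes)
qc$report
#> filter_report: 1200 in, 1153 out (call rate: -0, het: -8, MAF: -39)

geno <- prune_redundant(impute_naive(qc$matrix))$matrix
map_summary(geno, gap_threshold_kb = 500)
#> map_summary: mean adjacent distance 310.1 kb, max gap 2399.6 kb (chr05),
#> 233 gaps > 500 kb

# phenotypes from the clean matrix, adjusted means from the split-plot model
phe <- simulate_effects_and_phenotypes(simulate_genotypes(sc)$genotypes, sc)
tab <- derived_traits(phe$phenotypes)
am  <- adjusted_means(fit_split_plot(tab, "SHOOT"))
gxc_rank_correlation(am, "SHOOT")   # genotype-by-condition interaction
#> [1] 0.71
repeatability(tab, "SHOOT", "salt")
#> [1] 0.95

K <- linear_kernel(center_genotypes(simulate_genotypes(sc)$genotypes))
Y <- cbind(control = setNames(am$mean[am$condition == "control"],
                              am$genotype[am$condition == "control"]),
           salt    = am$mean[am$condition == "salt"])
parts <- make_partitions(150, n_reps = 10, seed = 7)
cv <- run_cv(K, Y, parts, model = "multi",
             cfg = gibbs_config(n_iter = 3000, burn_in = 500, thin = 5,
                                seed = 7),
             method = "GBLUP", trait = "SHOOT")
summarize_cv(cv)
#>   trait condition method model mean_pa  se_pa n_reps n_undefined
#> 1 SHOOT   control  GBLUP multi   0.355 0.0457     10           0
#> 2 SHOOT      salt  GBLUP multi   0.299 0.0259     10           0
```

Reading the output: the filter dropped 8 markers for excess heterozygosity
and 39 for low MAF; the simulated trait shows a control/salt rank
correlation of 0.71 (moderate genotype-by-condition interaction) and a
repeatability of 0.95 under salt; mean predictive ability over ten shared
partitions is ≈ 0.36 (control) and ≈ 0.30 (salt) with their standard
errors. Longer chains (the `gibbs_config()` defaults retain 3,000 of
35,000 iterations) and 100 partitions are recommended for real analyses.

A YAML-driven command-line interface wraps the same functions, stage by
stage (`simulate`, `qc`, `adjust`, `kernel`, `fit`, `cv`, `predict`,
`select`, `structure`):

```sh
saltgp simulate --config run.yaml
saltgp qc --config run.yaml
saltgp cv --config run.yaml --seed 11
```

Each stage writes its outputs plus a JSON-lines log (seeds, versions, wall
time) into the configured output directory.

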
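# ggxe

Environment-dependent epistatic networks and genetic capacitance in a
haploid cross.

## What this package is for

In a biparental haploid segregant panel — the motivating system is a yeast
cross phenotyped for growth on many media — every segregant is a fixed
recombinant genotype that can be measured with replication in each
environment. Growth there is shaped by additive locus effects, by epistatic
(G-by-G) interactions, and by the fact that the *activity* of those
interactions changes with the environment (G-by-G-by-E). A recurrent motif
is the *capacitor*: a highly connected hub locus whose genotype hides or
releases the allelic effects of its interacting (radial) loci, buffering
cryptic genetic variation that an allele substitution or an environment
shift exposes.

`ggxe` is for quantitative geneticists who want to run that entire analysis
chain on such a panel — or on synthetic panels with known ground truth:

* **Variance partition** (`partition_gxe`): two-way ANOVA of the replicate
  means, ȳᵢⱼ = u + idᵢ + Eⱼ + idᵢ×Eⱼ + e, reporting SS and fractions for G,
  E and G-by-E.
* **Additive locus set** (`marginal_scan`, `prune_loci`,
  `polygenic_select`, `estimate_effects`, `group_lrt`): linkage pruning
  (within 20 kb *and* r² > 0.9), per-environment joint fits Ȳ = Xβ + e with
  genotypes coded 0/2 (β is per allele copy), Benjamini–Hochberg selection
  at FDR 0.05, and a group LRT for the polygenic contribution of the
  individually non-significant loci.
* **QTL-by-environment tests** (`qtl_by_env_lrt`, `test_gxe_all`,
  `correct_gxe`): replicate-level models yᵢⱼₖ = u + Eⱼ + Σₓ aₓbₓ (+ Eⱼaₓβₓ)
  + e, compared by likelihood-ratio tests with χ²(E−1) reference and
  Bonferroni correction across loci.
* **Epistatic network** (`pairwise_lrt`, `retest_across_envs`,
  `build_network`, `find_hubs`, `hub_activity_profile`, `network_fit_rank`,
  `summarize_network`): pairwise interaction LRTs, lenient re-testing of
  discovered pairs in every environment (α divided by the number of
  discovered pairs), the across-environment multigraph, hubs (> 4
  interactors in one environment) and their activity profiles.
* **Capacitation** (`conditional_h2`, `genotype_class_env_lrt`,
  `decreasing_allele_profile`): narrow-sense heritability stratified by hub
  genotype (Δh² measures released cryptic variance), the 64-genotype-class
  by environment LRT, and growth against the count of growth-decreasing
  radial alleles.
* **Population dynamics** (`broad_sense_h2`, `env_variance_summary`,
  `effect_variance_by_locus`, `variance_vs_connectivity`,
  `hub_vs_nonhub_test`, `total_variance_vs_edges`, `noncapacitated_rank`):
  repeatability-based H², V_total = Vp·H², active edge counts n_ep per
  environment, and the regressions linking connectivity changes to
  additive-effect variance and total genetic variance.
* **Synthetic crosses** (`make_genetic_map`, `simulate_genotypes`,
  `simulate_phenotypes`, `make_paperlike_arch`): Haldane-map meiosis,
  environment-dependent additive/epistatic/capacitor architectures,
  replicate Gaussian noise, control-normalised growth.

`run_pipeline()` chains all stages with a YAML-able config, per-stage seeds
and a reproducibility manifest; `inst/cli/ggxe.R` is a thin command-line
wrapper. See the methods vignette (`vignettes/ggxe-methods.Rmd`) for the
models, assumptions and design choices.

## Worked example

```r
library(ggxe)
res <- run_pipeline(pipeline_config(
  seed = 7, n_segregants = 800, n_envs = 6,
  hub_spec = list(n_radials = 6)), out_dir = "ggxe_out")
```

This simulates an 800-segregant panel over 6 environments with one masking
hub (6 radial interactors, active in environments 1–2, silent in 3–6) over
8 background additive loci, then runs every stage. With seed 7 it prints
nothing, but the returned object and `ggxe_out/` contain:

```r
res$varcomp[c("fraction_G", "fraction_GxE")]
#> $fraction_G    0.320
#> $fraction_GxE  0.526
```

G-by-E carries more growth variance than G, as expected when interaction
activity is environment-switched.

```r
res$network$hubs
#> [1] "c01_m06"
res$capacitation[[1]][c("h2_allele0", "h2_allele2", "delta_h2")]
#> $h2_allele0 0.007   $h2_allele2 0.410   $delta_h2 0.403
```

The planted hub is recovered with all six interactors in its active
environment and none in the silent ones. Within segregants carrying the
masking hub allele the radial loci explain essentially no variance
(h² ≈ 0.01); the alternative allele releases them (h² ≈ 0.41) — about 0.4
units of narrow-sense heritability are capacitated.

```r
res$dynamics$summaries[, c("environment", "H2", "V_total", "n_ep")]
#>   environment    H2 V_total n_ep
#> 1       env01 0.547   1.220    6
#> 2       env02 0.551   1.278    6
#> 3       env03 0.252   0.294    0
#> ...
res$dynamics$variance_vs_connectivity[c("slope", "p")]  # 0.030, 3.4e-45
res$dynamics$total_variance_vs_edges[c("slope", "p")]   # 0.169, 1.1e-11
```

Environments where the hub's interactions are active express about a unit
more total genetic variance, and loci with more epistatic interactors show
more variable additive effects across environments — the population-level
signatures of G-by-G-by-E. (The pairwise-difference p-value is the nominal
one; environment pairs overlap, so use `n_perm > 0` for a calibrated
permutation p.)

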
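---
title: "Dissecting environment-dependent epistatic networks with ggxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting environment-dependent epistatic networks with ggxe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggxe)
```

## The problem

In a biparental haploid cross — the motivating system is a yeast segregant
panel grown on many different media — each segregant is a fixed recombinant
genotype that can be phenotyped with replication in every environment. Growth
is shaped not only by additive locus effects but by epistatic (G-by-G)
interactions, and the *activity* of those interactions can itself depend on
the environment (G-by-G-by-E). A recurring architecture is a *capacitor*: a
highly connected hub locus whose genotype hides or releases the allelic
effects of its interacting (radial) loci, so that one hub allele buffers
cryptic genetic variation that the other allele — or a change of environment —
exposes. `ggxe` implements the full analysis chain for such panels, plus a
simulator so that every stage can be exercised, calibrated and
power-checked against a known ground truth.

Growth phenotypes are assumed to be expressed as deviations from a control
medium, which removes the environment main effect in expectation; all models
nevertheless estimate and report the environment term.

## Models

Throughout, haploid genotypes are coded 0/2 for the two parental alleles, so
an additive effect is per allele copy.

**Variance partition.** `partition_gxe()` decomposes the per-(segregant,
environment) replicate means by a two-way factorial ANOVA,

$$\bar y_{ij} = u + \mathrm{id}_i + E_j + (\mathrm{id}\times E)_{ij} + e,$$

reporting the sums of squares for genotype, environment and their
interaction, and their fractions of the total. Because the response is the
cell mean of a complete layout, the three terms decompose the total exactly;
the residual is reported as the numerical remainder. Segregants without full
environment coverage are excluded (with a warning) to keep the layout
balanced — the alternative, unbalanced sequential sums of squares, would make
the G and G-by-E fractions order-dependent.

**Additive locus set.** The across-environment locus set is built in three
steps: a per-environment marginal scan (`marginal_scan()`, simple regression
on segregant means; this stands in for an imported QTL table when one is
available), linkage pruning (`prune_loci()`: peaks are merged only when they
are *both* within 20 kb *and* in genotype $r^2 > 0.9$; each cluster is
represented by its most significant peak, ties broken by the leftmost
coordinate), and a per-environment multi-locus selection
(`polygenic_select()`: one joint least-squares fit of all candidates on the
segregant means, Benjamini–Hochberg at FDR 0.05 on the per-locus t-tests).
BH is used because the upstream analyses name only an FDR level, not a
procedure; the joint fit is one-shot rather than backward elimination, which
keeps the selected set a deterministic function of the candidate set (a
backward pass can be added by refitting on the flagged subset). Joint
per-environment effects come from `estimate_effects()` — all loci fitted
simultaneously, each environment independently — and
`group_lrt()` tests whether the individually non-significant members of the
set still contribute polygenically in an environment.

**Likelihood-ratio tests.** All LRTs are Gaussian profiled-likelihood
ratios, $LR = n \log(\mathrm{RSS_{reduced}}/\mathrm{RSS_{full}})$, referred
to a $\chi^2$ with the parameter-count difference as degrees of freedom —
numerically identical to `lmtest::lrtest()` on the corresponding `lm` fits
(the test suite cross-checks this). The locus-by-environment test
(`qtl_by_env_lrt()`) works on replicate-level values with environment main
effects and *all* mapped loci fitted simultaneously, and compares the model
with an (environment x focal locus) interaction against the one without
(df = environments − 1). Because the reduced model is shared by every focal
locus, `test_gxe_all()` factorises it once and evaluates each interaction
block on the residualised scale (Frisch–Waugh), which is exact and makes a
311-locus screen tractable. Family-wise correction is Bonferroni across loci
(`correct_gxe()`); the correction choice is conservative and deliberate,
since the downstream claims count loci *with* significant interactions.

These LRTs assume i.i.d. homoscedastic residuals conditional on the fitted
loci. Unmodelled polygenic background violates that in two distinct ways
worth knowing about: loci *linked* to unmodelled causal variants acquire
real partial effects (inflating group tests), and unmodelled genetic
variance shared across an individual's replicates and environments makes
interaction tests conservative. The null-calibration suite therefore plants
all genetic signal inside the fitted loci; with real data the polygenic
fitting of the full locus set plays that role.

**Epistatic network.** `pairwise_lrt()` tests one pair in one environment on
segregant means: additive terms plus a product interaction versus additive
only ($\chi^2_1$); pairs with an empty two-locus genotype class are flagged
inestimable and count as inactive. `retest_across_envs()` re-tests every
discovered pair in every environment under a lenient threshold correcting
only for the number of discovered pairs (0.05/212 in a 212-pair study);
dividing additionally by the number of environments is available as
`correct_per_env = TRUE`, but the default follows the single-correction
reading of the design. A (pair, environment) record is active if it was a
discovery there or passes the lenient threshold. `build_network()` assembles
the multigraph (one edge per active record, parallel edges across
environments), and `find_hubs()` applies the strict rule "more than 4
distinct interactors in at least one single environment".
`hub_activity_profile()` fixes a hub's reference interactor set in its most
activated environment (ties broken by the alphabetically first label,
logged in the report) and tracks the fraction of that set that stays
epistatically active, or retains a significant additive effect, in each
other environment. `network_fit_rank()` ranks hub networks within each
environment by the adjusted $r^2$ of the joint additive-plus-hub-interaction
model. For the variance-explained summary (`summarize_network()`) the
"fraction of additive genetic variance explained" divides the network-loci
model's adjusted $r^2$ by the full locus-set model's, both clamped at zero
and the ratio capped at one; the numerator is reported alongside because the
denominator is itself an estimate.

**Capacitation.** `conditional_h2()` stratifies the panel by the hub
genotype and fits the radial loci jointly within each stratum; the
stratified narrow-sense heritability is the adjusted $r^2$ of that fit,
clamped to [0, 1]. Adjusted rather than raw $r^2$ avoids the stratum-size
bias (the two strata need not be equally large), at the cost of a slight
downward bias near zero where the clamp binds. `genotype_class_env_lrt()`
generalises the locus-by-environment LRT to the joint genotype class of up
to six loci (64 classes in a haploid cross); unobserved classes are dropped
and reported, and the degrees of freedom are computed as the design-rank
difference, which equals (classes − 1)(environments − 1) when all cells are
observed. `decreasing_allele_profile()` scores each segregant by its count
of growth-decreasing radial alleles — signs taken from the joint additive
fit *in that environment*, since allele effects may flip sign across
environments — split by hub genotype.

**Population-level dynamics.** `broad_sense_h2()` estimates repeatability
from the one-way ANOVA of replicates, $H^2 = (MS_B - MS_W)/(MS_B + (\bar k -
1) MS_W)$, clamped to [0, 1]. In `env_variance_summary()` the narrow-sense
$h^2$ is the additive variance captured by the joint locus fit on segregant
means (adjusted $r^2$ times the variance of means), divided by the
replicate-level phenotypic variance — this keeps $h^2$ on the same scale as
$H^2$, so the invariant $h^2 \le H^2$ holds up to estimation noise. Total
genetic variance is $V_\mathrm{total} = V_p \times H^2$, and `n_ep` counts
active epistatic *edges* (not endpoint incidences) per environment.
`effect_variance_by_locus()` takes the sample variance of each locus's
joint-model effect across all environments (significant or not);
`variance_vs_connectivity()` regresses it on the locus's maximum interactor
count, and `hub_vs_nonhub_test()` compares hub and non-hub loci by a
two-sided Wilcoxon rank-sum test (normal approximation with tie
correction). `noncapacitated_rank()` ranks segregants within each
environment (rank 1 = best growth, ties averaged), averages ranks across
environments and tabulates them against the count of non-masking hub
alleles.

**Environment-pair regression and its p-value.** `total_variance_vs_edges()`
regresses $\Delta V_\mathrm{total}$ on $\Delta n_{ep}$ over all unordered
environment pairs (ordered lexicographically, earlier minus later; the slope
is sign-symmetric under the opposite convention). The pairs share
environments, so the nominal regression p-value is anticonservative: with
$E$ environments the true sampling variance of the slope is roughly $E/2$
times the OLS formula's, inflating $|z|$ by about $\sqrt{E/2}$. The function
reports the nominal p (the procedure as printed) and, with `n_perm > 0`, a
calibrated p obtained by permuting the environment labels of the edge
counts, which is exact under the exchangeability null. Calibration checks in
the test suite use the permutation p; power statements use the nominal p.
When validating the calibration by simulation, $V_\mathrm{total}$ and
$n_{ep}$ are estimated from *independent* panels: estimated from the same
phenotypes they share sampling noise (a sample that exaggerates genetic
differences inflates both $H^2$ and edge detection), which is a genuine
dependence of the estimates, not a defect of the test.

## The synthetic-cross generator

`simulate_genotypes()` drops haploid recombinants through a genetic map
with the Haldane (no interference) map function: adjacent markers $d$ cM
apart recombine with probability $r = \tfrac12(1 - e^{-2d/100})$, and
chromosomes segregate independently. `simulate_phenotypes()` adds, per
environment: additive terms (effect x genotype), pairwise epistatic terms
(effect x $g_A g_B/4$, i.e. the stated effect when both loci carry allele
2), capacitor radial terms (effect x genotype, contributing only where the
hub carries the non-masking allele) and i.i.d. Gaussian replicate noise.
Replicate noise is homoscedastic Gaussian because every fitted model assumes
exactly that; the residual distribution of real growth measurements is not
known to be Gaussian, so calibration statements are statements about the
model's own assumptions. The environment main effect defaults to zero
(control-normalised growth) but accepts a nonzero override for robustness
checks.

`make_paperlike_arch()` builds the canonical study design: one hub with six
radial interactors, fully active in some environments and fully silent in
others (optionally half-active in between), over a background of additive
loci with environment-constant effects, on a 16-chromosome map with causal
loci placed on distinct chromosomes so planted architectures are unlinked by
construction. Defaults — radial effect 0.3 growth units per allele copy,
residual SD 1, two replicates — give per-locus signals comparable to a
mid-sized QTL and a released-stratum heritability near 0.35 with six
radials, which is the regime the method is meant for. What the generator
does *not* emulate: genotyping error, crossover interference, dominance (the
cross is haploid), segregation distortion, heteroscedastic or heavy-tailed
measurement noise, and shared environmental (plate/batch) structure.
Passing tests therefore demonstrate correctness and calibration under the
models' assumptions, not robustness to those violations.

## Numerical and design choices

* Sizing of the simulation-based checks is chosen for stable statistics on a
  single CPU: 1000 null replicates for type-I calibration at n = 500 and 5
  environments, 200 replicates for estimator bias/SE, 50–150 replicates for
  recovery and sign checks at n = 1000–4000. The genotype-class-by-
  environment null calibration uses 3 loci (8 classes, df = 28): a 64-class
  interaction LRT has far too many parameters for its $\chi^2$ asymptotics
  at n = 500, in any implementation.
* Ranks use `ties.method = "first"` where a strict permutation 1..K is
  required (network fit ranks) and average ranks for growth ranking.
* Degenerate inputs: monomorphic markers are flagged with p = 1; pairs with
  an empty genotype class are inestimable-inactive; rank-deficient joint
  designs name the collinear loci (pruning should prevent them); aliased
  columns in exploratory network fits are dropped with a warning.
* All randomness flows through explicit integer seeds; the pipeline derives
  per-stage seeds from the one seed in its config, and identical configs
  reproduce byte-identical outputs.
* The pipeline seeds its interaction re-test from the simulated truth's
  pair list, mirroring a study that imports previously discovered
  interaction tables rather than re-scanning all marker pairs; a de novo
  two-locus genome scan is out of scope.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(pipeline_config(
  seed = 7, n_segregants = 800, n_envs = 6,
  hub_spec = list(n_radials = 6)), out_dir = "ggxe_out")

res$varcomp$fraction_GxE          # G-by-E share of growth variance
res$network$hubs                  # recovered hub loci
res$capacitation[[1]]$delta_h2    # heritability released by the hub allele
res$dynamics$total_variance_vs_edges$slope
```

On this 800-segregant, 6-environment panel the planted hub is recovered
with six interactors in its active environments and none in the silent
ones; the stratified heritability difference is about 0.4 (radial variance
6 x 0.09 against a residual of ~1.2 including background), and both
dynamics regressions have positive slopes.

## Limitations

The LRT calibration is asymptotic; at a few hundred segregants the
$\chi^2$ reference is slightly anticonservative (size ~0.052 at n = 500 for
1 df). The environment-pair regression's nominal p should be read as a
descriptive statistic, with the permutation p as the inferential one. The
lenient re-test rule conditions on the discovered pair list and therefore
inherits any winner's-curse bias in the discovery scan. Stratified
heritabilities are clamped adjusted $r^2$ values, slightly biased near the
boundary. None of the models account for shared environmental structure
among replicates.
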
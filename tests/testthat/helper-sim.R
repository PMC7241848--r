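# Shared fixture builders. All fixtures are generated in code.

# n_markers unlinked markers: one marker per chromosome
unlinked_map <- function(n_markers) {
  make_genetic_map(n_chrom = n_markers, markers_per_chrom = 1)
}

# architecture with the same additive effect for each locus in every
# environment (no G-by-E, no epistasis)
constant_additive_arch <- function(envs, loci, effects, residual_sd = 1,
                                   replicates = 2, map = NULL) {
  sim_architecture(
    environments = envs,
    additive = data.frame(locus = rep(loci, each = length(envs)),
                          environment = rep(envs, length(loci)),
                          effect = rep(effects, each = length(envs)),
                          stringsAsFactors = FALSE),
    residual_sd = residual_sd, replicates = replicates, map = map)
}

# one masking hub + radial loci, fully active in `active_envs`, silent
# elsewhere
capacitor_arch <- function(envs, hub, radials, effect, active_envs,
                           masking_allele = 0, residual_sd = 1,
                           replicates = 1, map = NULL) {
  rows <- do.call(rbind, lapply(envs, function(e) {
    data.frame(locus = radials, environment = e,
               effect = if (e %in% active_envs) effect else 0,
               stringsAsFactors = FALSE)
  }))
  sim_architecture(environments = envs,
                   capacitors = list(list(hub = hub,
                                          masking_allele = masking_allele,
                                          radials = rows)),
                   residual_sd = residual_sd, replicates = replicates,
                   map = map)
}

# hand-built interaction records for network-shape tests
make_records <- function(pairs, envs, active = TRUE) {
  data.frame(locusA = vapply(pairs, `[[`, "", 1L),
             locusB = vapply(pairs, `[[`, "", 2L),
             environment = envs, LR = 10, p = 1e-4,
             estimable = TRUE, discovery = FALSE, active = active,
             stringsAsFactors = FALSE)
}

# 95% binomial CI half-width around p0
binom_ci_halfwidth <- function(p0, n) 1.96 * sqrt(p0 * (1 - p0) / n)
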
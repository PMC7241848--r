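#' Define a simulation architecture
#'
#' A `sim_architecture` is the ground-truth generative specification for a
#' synthetic haploid segregant panel: environment-dependent additive effects,
#' environment-dependent pairwise epistatic effects, capacitor (hub-masking)
#' structures, replicate measurement noise and the replicate count.
#'
#' Genotypes are coded 0/2 for the two parental alleles, so an additive
#' `effect` is the change in growth per allele copy. A pairwise epistatic
#' effect contributes `effect * gA * gB / 4`, i.e. the full `effect` when a
#' segregant carries allele 2 at both loci. A capacitor radial effect
#' contributes `effect * g_radial` only in segregants whose hub genotype
#' differs from `masking_allele`; in the masked stratum the radial locus is
#' phenotypically silent (cryptic).
#'
#' @param environments character vector of environment labels.
#' @param additive data frame (`locus`, `environment`, `effect`); may be NULL.
#' @param epistatic data frame (`locusA`, `locusB`, `environment`, `effect`);
#'   may be NULL.
#' @param capacitors list; each element a list with `hub` (marker id),
#'   `masking_allele` (0 or 2) and `radials`, a data frame
#'   (`locus`, `environment`, `effect`). May be empty.
#' @param residual_sd replicate noise standard deviation; a scalar or a named
#'   vector with one entry per environment. Must be positive.
#' @param replicates replicates per segregant and environment (>= 1).
#' @param env_main environment main effects (growth already normalised
#'   against a control medium has none; default 0). Scalar or named vector.
#' @param map optional genetic map the loci must belong to.
#' @return an object of class `sim_architecture`.
#' @export
sim_architecture <- function(environments, additive = NULL, epistatic = NULL,
                             capacitors = list(), residual_sd = 1,
                             replicates = 2, env_main = 0, map = NULL) {
  environments <- as.character(environments)
  if (length(environments) < 1L) stop("at least one environment required")
  empty_add <- data.frame(locus = character(), environment = character(),
                          effect = numeric(), stringsAsFactors = FALSE)
  empty_epi <- data.frame(locusA = character(), locusB = character(),
                          environment = character(), effect = numeric(),
                          stringsAsFactors = FALSE)
  arch <- structure(list(
    environments = environments,
    additive = if (is.null(additive)) empty_add else additive,
    epistatic = if (is.null(epistatic)) empty_epi else epistatic,
    capacitors = capacitors,
    residual_sd = residual_sd,
    replicates = as.integer(replicates),
    env_main = env_main,
    map = map
  ), class = "sim_architecture")
  validate_architecture(arch)
  arch
}

#' Validate a simulation architecture
#'
#' @param arch a `sim_architecture`.
#' @return the architecture, invisibly; stops on violation.
#' @export
validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "sim_architecture"))
  if (any(arch$residual_sd <= 0)) stop("residual_sd must be positive")
  if (arch$replicates < 1L) stop("replicates must be >= 1")
  bad_env <- setdiff(
    c(arch$additive$environment, arch$epistatic$environment,
      unlist(lapply(arch$capacitors, function(cp) cp$radials$environment))),
    arch$environments)
  if (length(bad_env) > 0L) {
    stop("effects reference undeclared environments: ",
         paste(unique(bad_env), collapse = ", "))
  }
  for (cp in arch$capacitors) {
    if (!cp$masking_allele %in% c(0, 2)) {
      stop("capacitor masking allele must be 0 or 2")
    }
    if (cp$hub %in% cp$radials$locus) {
      stop("capacitor radial loci must exclude the hub (", cp$hub, ")")
    }
  }
  if (!is.null(arch$map)) {
    loci <- arch_loci(arch)
    missing <- setdiff(loci, arch$map$marker)
    if (length(missing) > 0L) {
      stop("architecture loci absent from the map: ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(arch)
}

#' All loci referenced by an architecture
#' @param arch a `sim_architecture`.
#' @return character vector of marker ids.
#' @export
arch_loci <- function(arch) {
  unique(c(arch$additive$locus, arch$epistatic$locusA, arch$epistatic$locusB,
           unlist(lapply(arch$capacitors,
                         function(cp) c(cp$hub, cp$radials$locus)))))
}

#' Candidate interaction pairs implied by an architecture
#'
#' Returns the locus pairs carrying a planted interaction (explicit epistatic
#' pairs plus hub-radial capacitor pairs) together with one environment in
#' which each is active; these play the role of an imported prior
#' interaction table when analysing a synthetic panel.
#'
#' @param arch a `sim_architecture`.
#' @return data frame (`locusA`, `locusB`, `environment`).
#' @export
truth_pairs <- function(arch) {
  out <- list()
  if (nrow(arch$epistatic) > 0L) {
    act <- arch$epistatic[arch$epistatic$effect != 0, , drop = FALSE]
    out[[length(out) + 1L]] <- act[!duplicated(.pair_key(act$locusA, act$locusB)),
                                   c("locusA", "locusB", "environment")]
  }
  for (cp in arch$capacitors) {
    act <- cp$radials[cp$radials$effect != 0, , drop = FALSE]
    if (nrow(act) > 0L) {
      first <- act[!duplicated(act$locus), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        locusA = cp$hub, locusB = first$locus,
        environment = first$environment, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(locusA = character(), locusB = character(),
                      environment = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[!duplicated(.pair_key(res$locusA, res$locusB)), , drop = FALSE]
}

#' Simulate haploid segregant genotypes
#'
#' Drops haploid recombinant genotypes through a genetic map using the
#' Haldane (no interference) map function: adjacent markers `d` cM apart
#' recombine with probability `r = (1 - exp(-2 d / 100)) / 2`. Chromosomes
#' segregate independently; the first marker of each chromosome receives
#' either parental allele with probability 1/2. Alleles are coded 0/2.
#'
#' @param n_segregants number of segregants (>= 1).
#' @param map a genetic map (see [make_genetic_map()]).
#' @param seed optional integer seed.
#' @return matrix of 0/2 values, segregants x markers, with dimnames.
#' @export
#' @examples
#' g <- simulate_genotypes(100, make_genetic_map(2, 5), seed = 1)
simulate_genotypes <- function(n_segregants, map, seed = NULL) {
  validate_genetic_map(map)
  if (n_segregants < 1) stop("n_segregants must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_segregants)
  chroms <- unique(map$chrom)
  geno <- matrix(0L, nrow = n, ncol = nrow(map),
                 dimnames = list(sprintf("seg%05d", seq_len(n)), map$marker))
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    state <- stats::rbinom(n, 1L, 0.5)
    geno[, idx[1L]] <- 2L * state
    if (m > 1L) {
      d <- diff(map$pos_cM[idx])
      r <- (1 - exp(-2 * d / 100)) / 2
      for (j in seq_len(m - 1L)) {
        sw <- stats::rbinom(n, 1L, r[j])
        state <- (state + sw) %% 2L
        geno[, idx[j + 1L]] <- 2L * state
      }
    }
  }
  geno
}

#' Simulate replicated growth phenotypes
#'
#' Generates growth values (deviations from a control medium) as the sum of
#' the architecture's environment main effect, additive terms
#' (`effect * genotype`), pairwise epistatic terms (`effect * gA * gB / 4`),
#' capacitor-masked radial terms (`effect * g_radial` only where the hub
#' carries the non-masking allele) and i.i.d. Gaussian replicate noise.
#'
#' @param geno genotype matrix from [simulate_genotypes()].
#' @param arch a `sim_architecture`.
#' @param seed optional integer seed.
#' @return long-format data frame (`segregant`, `environment`, `replicate`,
#'   `growth`).
#' @export
simulate_phenotypes <- function(geno, arch, seed = NULL) {
  validate_architecture(arch)
  .check_geno_loci(geno, arch_loci(arch), "architecture locus")
  if (!is.null(seed)) set.seed(seed)
  envs <- arch$environments
  n <- nrow(geno)
  nE <- length(envs)
  sd_env <- rep(arch$residual_sd, length.out = nE)
  if (!is.null(names(arch$residual_sd)) && length(arch$residual_sd) > 1L) {
    sd_env <- arch$residual_sd[envs]
  }
  mu_env <- rep(arch$env_main, length.out = nE)
  if (!is.null(names(arch$env_main)) && length(arch$env_main) > 1L) {
    mu_env <- arch$env_main[envs]
  }
  G <- matrix(rep(as.numeric(mu_env), each = n), nrow = n,
              dimnames = list(rownames(geno), envs))
  if (nrow(arch$additive) > 0L) {
    for (i in seq_len(nrow(arch$additive))) {
      row <- arch$additive[i, ]
      G[, row$environment] <- G[, row$environment] +
        row$effect * geno[, row$locus]
    }
  }
  if (nrow(arch$epistatic) > 0L) {
    for (i in seq_len(nrow(arch$epistatic))) {
      row <- arch$epistatic[i, ]
      G[, row$environment] <- G[, row$environment] +
        row$effect * geno[, row$locusA] * geno[, row$locusB] / 4
    }
  }
  for (cp in arch$capacitors) {
    open <- geno[, cp$hub] != cp$masking_allele
    for (i in seq_len(nrow(cp$radials))) {
      row <- cp$radials[i, ]
      G[open, row$environment] <- G[open, row$environment] +
        row$effect * geno[open, row$locus]
    }
  }
  k <- arch$replicates
  reps <- lapply(seq_len(k), function(r) {
    noise <- matrix(stats::rnorm(n * nE, 0, rep(sd_env, each = n)), nrow = n)
    data.frame(
      segregant = rep(rownames(geno), times = nE),
      environment = rep(envs, each = n),
      replicate = r,
      growth = as.numeric(G + noise),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

#' Build a hub-capacitor architecture with environment-switched activity
#'
#' Convenience builder for the study design explored throughout the package:
#' one highly connected hub locus whose interactions with a set of radial
#' loci are fully active in at least one environment and fully inactive in at
#' least one other, on top of background additive loci whose effects are
#' constant across environments. In intermediate environments roughly half
#' the radial interactions stay active, mimicking the gradual rewiring seen
#' when growth conditions become more dissimilar.
#'
#' @param n_envs number of environments (>= 2).
#' @param hub_spec list of optional overrides: `n_radials` (default 6),
#'   `radial_effect` (0.3 growth units per allele copy), `masking_allele`
#'   (0), `n_background` (8 additive loci), `background_effect` (0.15),
#'   `hub_additive` (0), `n_active_envs` (number of fully active
#'   environments, default `ceiling(n_envs / 3)`), `n_partial_envs`
#'   (default 0), `residual_sd` (1), `replicates` (2).
#' @param seed optional integer seed (used to place loci on the map).
#' @param map optional genetic map; by default a 5-chromosome, 60-marker map
#'   at 10 cM spacing is created.
#' @return a `sim_architecture` with the map attached.
#' @export
#' @examples
#' arch <- make_paperlike_arch(3, list(n_radials = 6), seed = 1)
make_paperlike_arch <- function(n_envs = 3, hub_spec = list(), seed = NULL,
                                map = NULL) {
  if (n_envs < 2) stop("n_envs must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  spec <- utils::modifyList(list(
    n_radials = 6, radial_effect = 0.3, masking_allele = 0,
    n_background = 8, background_effect = 0.15, hub_additive = 0,
    n_active_envs = max(1L, ceiling(n_envs / 3)), n_partial_envs = 0,
    residual_sd = 1, replicates = 2
  ), hub_spec)
  if (is.null(map)) map <- make_genetic_map(16, 12, 10)
  envs <- sprintf("env%02d", seq_len(n_envs))
  n_needed <- 1L + spec$n_radials + spec$n_background
  if (n_needed > nrow(map)) {
    stop("hub_spec requests ", n_needed, " loci but the map has only ",
         nrow(map), " markers")
  }
  # place causal loci so they are as unlinked as possible: cycle over the
  # chromosomes, and within a chromosome reuse positions spaced at least
  # half a chromosome apart (middle first, then the two ends)
  chroms <- unique(map$chrom)
  per_chrom <- split(seq_len(nrow(map)), map$chrom)[chroms]
  slot_order <- function(m) {
    mid <- ceiling(m / 2)
    unique(c(mid, 1L, m, pmin(m, mid + seq_len(m))))[seq_len(m)]
  }
  picks <- character(0)
  round_i <- 1L
  while (length(picks) < n_needed) {
    for (ch in chroms) {
      idx <- per_chrom[[ch]]
      slots <- slot_order(length(idx))
      if (round_i <= length(slots)) {
        picks <- c(picks, map$marker[idx[slots[round_i]]])
      }
      if (length(picks) >= n_needed) break
    }
    round_i <- round_i + 1L
    if (round_i > max(lengths(per_chrom))) break
  }
  if (length(picks) < n_needed) picks <- map$marker[seq_len(n_needed)]
  hub <- picks[1L]
  radials <- picks[1L + seq_len(spec$n_radials)]
  background <- picks[1L + spec$n_radials + seq_len(spec$n_background)]
  n_act <- min(spec$n_active_envs, n_envs - 1L)
  active_envs <- envs[seq_len(n_act)]
  partial_envs <- if (spec$n_partial_envs > 0)
    envs[n_act + seq_len(min(spec$n_partial_envs, n_envs - n_act - 1L))]
  else character()
  radial_rows <- do.call(rbind, lapply(envs, function(e) {
    eff <- if (e %in% active_envs) {
      rep(spec$radial_effect, spec$n_radials)
    } else if (e %in% partial_envs) {
      spec$radial_effect * (seq_len(spec$n_radials) %% 2L)
    } else rep(0, spec$n_radials)
    data.frame(locus = radials, environment = e, effect = eff,
               stringsAsFactors = FALSE)
  }))
  additive <- do.call(rbind, lapply(envs, function(e) {
    data.frame(locus = background, environment = e,
               effect = rep(spec$background_effect,
                            length.out = spec$n_background),
               stringsAsFactors = FALSE)
  }))
  if (spec$hub_additive != 0) {
    additive <- rbind(additive, do.call(rbind, lapply(envs, function(e) {
      data.frame(locus = hub, environment = e, effect = spec$hub_additive,
                 stringsAsFactors = FALSE)
    })))
  }
  sim_architecture(
    environments = envs,
    additive = additive,
    capacitors = list(list(hub = hub, masking_allele = spec$masking_allele,
                           radials = radial_rows)),
    residual_sd = spec$residual_sd,
    replicates = spec$replicates,
    map = map
  )
}
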
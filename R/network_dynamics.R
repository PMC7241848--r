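#' Broad-sense heritability from replicate repeatability
#'
#' One-way ANOVA of the replicate-level growth values across segregants in
#' one environment. With between- and within-segregant mean squares MSB and
#' MSW and mean replicate number k, the repeatability estimate is
#' `H2 = (MSB - MSW) / (MSB + (k - 1) MSW)`, clamped to [0, 1]. The
#' phenotypic variance `Vp` is the variance of the replicate-level values.
#'
#' @param pheno phenotype table.
#' @param environment environment label.
#' @return list (`Vp`, `H2`, `MS_between`, `MS_within`, `k_mean`).
#' @export
broad_sense_h2 <- function(pheno, environment) {
  ph <- pheno[pheno$environment == environment, , drop = FALSE]
  if (nrow(ph) == 0L) stop("environment '", environment, "' not found")
  k_i <- table(ph$segregant)
  if (mean(k_i >= 2) < 0.5) {
    stop("broad-sense H2 needs >= 2 replicates for at least half the ",
         "segregants in ", environment)
  }
  means <- tapply(ph$growth, ph$segregant, mean)
  grand <- mean(ph$growth)
  N <- nrow(ph)
  I <- length(means)
  SSB <- sum(k_i * (means[names(k_i)] - grand)^2)
  SSW <- sum((ph$growth - means[ph$segregant])^2)
  MSB <- SSB / (I - 1)
  MSW <- SSW / (N - I)
  k_mean <- mean(k_i)
  H2 <- (MSB - MSW) / (MSB + (k_mean - 1) * MSW)
  list(Vp = stats::var(ph$growth), H2 = min(1, max(0, H2)),
       MS_between = MSB, MS_within = MSW, k_mean = k_mean)
}

#' Per-environment variance summary
#'
#' For each environment: the phenotypic variance `Vp` and broad-sense `H2`
#' (from [broad_sense_h2()]); the narrow-sense `h2`, computed as the additive
#' variance captured by the joint locus fit on segregant means
#' (adjusted r-squared times the variance of the means) divided by `Vp`, so
#' that it is on the replicate-level scale and cannot exceed `H2` beyond
#' estimation noise; the total genetic variance `V_total = Vp * H2`; and the
#' number of active epistatic edges `n_ep` when a network is supplied.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param loci additive locus set (a `locus_set` or character vector).
#' @param net optional `epistatic_network` supplying `n_ep`.
#' @return data frame (`environment`, `Vp`, `H2`, `h2`, `V_total`, `n_ep`).
#' @export
env_variance_summary <- function(geno, pheno, loci, net = NULL) {
  ids <- if (inherits(loci, "locus_set")) loci$loci else as.character(loci)
  envs <- .environments(pheno)
  out <- do.call(rbind, lapply(envs, function(e) {
    bh <- broad_sense_h2(pheno, e)
    al <- .segregant_means(geno, pheno, e)
    fit <- .ols(cbind(1, al$G[, ids, drop = FALSE]), al$y,
                allow_aliased = TRUE)
    Va <- max(0, fit$adj_r2) * stats::var(al$y)
    data.frame(environment = e, Vp = bh$Vp, H2 = bh$H2,
               h2 = min(1, Va / bh$Vp), V_total = bh$Vp * bh$H2,
               stringsAsFactors = FALSE)
  }))
  out$n_ep <- if (!is.null(net)) {
    act <- net$records[net$records$active, , drop = FALSE]
    as.integer(table(factor(act$environment, levels = envs)))
  } else NA_integer_
  rownames(out) <- NULL
  out
}

#' Across-environment variance of additive effects, with connectivity
#'
#' Computes, per locus, the sample variance of the joint-model additive
#' effect estimates across environments (all environments, significant or
#' not) and attaches the locus's maximum epistatic interactor count across
#' environments plus a hub flag.
#'
#' @param additive additive effect table from [estimate_effects()].
#' @param net optional `epistatic_network`; loci absent from the network get
#'   count 0.
#' @param hubs optional explicit hub ids (default [find_hubs()] on `net`).
#' @return data frame (`locus`, `effect_variance`, `max_interactors`, `hub`).
#' @export
effect_variance_by_locus <- function(additive, net = NULL, hubs = NULL) {
  n_env <- length(unique(additive$environment))
  if (n_env < 2L) stop("effects must be estimated in >= 2 environments")
  agg <- stats::aggregate(effect ~ locus, data = additive, FUN = stats::var)
  names(agg)[2L] <- "effect_variance"
  agg$max_interactors <- 0L
  if (!is.null(net)) {
    mx <- apply(net$interactor_counts, 1L, max)
    hit <- agg$locus %in% names(mx)
    agg$max_interactors[hit] <- as.integer(mx[agg$locus[hit]])
    if (is.null(hubs)) hubs <- find_hubs(net)
  }
  agg$hub <- agg$locus %in% (hubs %||% character())
  agg
}

#' Regression of additive-effect variance on epistatic connectivity
#'
#' Simple linear regression of the per-locus across-environment variance of
#' additive effects on the locus's maximum number of active epistatic
#' interactors, with a two-sided t test on the slope. A positive slope means
#' loci whose network connectivity changes more show more variable marginal
#' additive effects.
#'
#' @param dyn data frame from [effect_variance_by_locus()].
#' @return list (`slope`, `se`, `p`, `n`).
#' @export
variance_vs_connectivity <- function(dyn) {
  if (nrow(dyn) < 3L) stop("need at least 3 loci")
  if (stats::var(dyn$max_interactors) == 0) {
    stop("interactor counts are constant; the regression is undefined")
  }
  fit <- .ols(cbind(1, x = dyn$max_interactors), dyn$effect_variance)
  list(slope = unname(fit$coef[2L]), se = unname(fit$se[2L]),
       p = unname(fit$p[2L]), n = nrow(dyn))
}

#' Wilcoxon rank-sum test: hub vs non-hub effect variance
#'
#' Two-sided Wilcoxon rank-sum test comparing the across-environment
#' additive-effect variances of hub loci against non-hub loci (normal
#' approximation with tie correction).
#'
#' @param dyn data frame from [effect_variance_by_locus()].
#' @return list (`W`, `p`, `n_hub`, `n_nonhub`).
#' @export
hub_vs_nonhub_test <- function(dyn) {
  x <- dyn$effect_variance[dyn$hub]
  y <- dyn$effect_variance[!dyn$hub]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both hub and non-hub groups must be non-empty")
  }
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  list(W = unname(wt$statistic), p = wt$p.value,
       n_hub = length(x), n_nonhub = length(y))
}

#' Pairwise-difference regression of total genetic variance on edge counts
#'
#' For all unordered environment pairs (ordered lexicographically, earlier
#' minus later), regresses the difference in total genetic variance
#' `V_total` on the difference in active epistatic edge counts `n_ep` and
#' reports the slope with its nominal regression p-value. The environment
#' pairs share environments and are therefore not independent, which makes
#' the nominal p anticonservative; with `n_perm > 0` a calibrated p-value is
#' additionally computed by permuting the environment labels of `n_ep`
#' (exchangeability null) and comparing absolute slopes.
#'
#' @param summaries data frame from [env_variance_summary()] (needs
#'   `environment`, `V_total`, `n_ep`).
#' @param n_perm number of label permutations for the calibrated p
#'   (default 0 = nominal only).
#' @return list (`slope`, `se`, `p` nominal, `p_perm` or NA, `n_pairs`).
#' @export
total_variance_vs_edges <- function(summaries, n_perm = 0) {
  s <- summaries[order(summaries$environment), , drop = FALSE]
  E <- nrow(s)
  if (E < 3L) stop("need at least 3 environments")
  ij <- utils::combn(E, 2L)
  dV <- s$V_total[ij[1L, ]] - s$V_total[ij[2L, ]]
  slope_of <- function(nep) {
    dn <- nep[ij[1L, ]] - nep[ij[2L, ]]
    if (stats::var(dn) == 0) return(NULL)
    .ols(cbind(1, dn = dn), dV)
  }
  fit <- slope_of(s$n_ep)
  if (is.null(fit)) stop("edge counts are constant across environments")
  p_perm <- NA_real_
  if (n_perm > 0) {
    obs <- abs(fit$coef[2L])
    hits <- 0L
    valid <- 0L
    for (b in seq_len(n_perm)) {
      pf <- slope_of(sample(s$n_ep))
      if (is.null(pf)) next
      valid <- valid + 1L
      if (abs(pf$coef[2L]) >= obs) hits <- hits + 1L
    }
    p_perm <- (hits + 1) / (valid + 1)
  }
  list(slope = unname(fit$coef[2L]), se = unname(fit$se[2L]),
       p = unname(fit$p[2L]), p_perm = p_perm, n_pairs = ncol(ij))
}

#' Mean growth rank by the number of non-capacitating hub alleles
#'
#' Ranks segregants within each environment by their mean growth (rank 1 =
#' best growth, ties averaged), averages the ranks across environments, and
#' scores each segregant by how many hub loci carry the non-capacitating
#' (releasing) allele. Segregants with more releasing hub alleles are
#' expected to grow better on average.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param hubs data frame (`hub`, `masking_allele`).
#' @return data frame (`segregant`, `n_noncapacitating`, `mean_rank`).
#' @export
noncapacitated_rank <- function(geno, pheno, hubs) {
  stopifnot(all(c("hub", "masking_allele") %in% names(hubs)))
  .check_geno_loci(geno, hubs$hub, "hub locus")
  envs <- .environments(pheno)
  ranks <- lapply(envs, function(e) {
    al <- .segregant_means(geno, pheno, e)
    r <- rank(-al$y, ties.method = "average")
    stats::setNames(r, al$ids)
  })
  ids <- Reduce(intersect, lapply(ranks, names))
  mean_rank <- rowMeans(do.call(cbind, lapply(ranks, function(r) r[ids])))
  n_rel <- rowSums(vapply(seq_len(nrow(hubs)), function(i)
    geno[ids, hubs$hub[i]] != hubs$masking_allele[i], logical(length(ids))))
  data.frame(segregant = ids, n_noncapacitating = as.integer(n_rel),
             mean_rank = as.numeric(mean_rank), stringsAsFactors = FALSE,
             row.names = NULL)
}
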
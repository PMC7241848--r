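#' Partition growth variance into genotype and genotype-by-environment parts
#'
#' Two-way factorial ANOVA decomposition of the per-(segregant, environment)
#' replicate means: growth is modelled as a grand mean plus a segregant
#' (genotype, G) term, an environment (E) term and their interaction (G-by-E).
#' Because the response is the cell mean, the decomposition is the balanced
#' closed form: `SS_G` from segregant means, `SS_E` from environment means,
#' `SS_GxE` from the interaction residuals, and `SS_total` their sum (the
#' numerical remainder is reported as `SS_resid`). Growth values normalised
#' against a control medium typically show a null environment main effect;
#' `SS_E` is computed and reported regardless.
#'
#' Segregants observed in fewer than two environments are excluded (their
#' interaction term is undefined) with a warning, as are segregants with
#' incomplete environment coverage relative to the panel, so that the
#' decomposition stays balanced.
#'
#' @param pheno long-format phenotype data frame
#'   (`segregant`, `environment`, `replicate`, `growth`).
#' @return a list of class `varcomp` with sums of squares `SS_G`, `SS_E`,
#'   `SS_GxE`, `SS_resid`, `SS_total`, the proportions `fraction_G`,
#'   `fraction_E`, `fraction_GxE`, the grand mean, and the panel dimensions.
#' @export
#' @examples
#' arch <- make_paperlike_arch(4, list(n_radials = 3, n_background = 4))
#' g <- simulate_genotypes(200, arch$map, seed = 1)
#' p <- simulate_phenotypes(g, arch, seed = 2)
#' partition_gxe(p)$fraction_GxE
partition_gxe <- function(pheno) {
  envs <- .environments(pheno)
  if (length(envs) < 2L) stop("at least two environments are required")
  cell <- tapply(pheno$growth, list(pheno$segregant, pheno$environment), mean)
  n_obs_env <- rowSums(!is.na(cell))
  drop <- rownames(cell)[n_obs_env < length(envs)]
  if (length(drop) > 0L) {
    warning(length(drop), " segregant(s) without complete environment ",
            "coverage excluded from the G/GxE partition")
    cell <- cell[n_obs_env == length(envs), , drop = FALSE]
  }
  if (nrow(cell) < 2L) stop("at least two fully observed segregants required")
  n_seg <- nrow(cell)
  n_env <- ncol(cell)
  grand <- mean(cell)
  m_seg <- rowMeans(cell)
  m_env <- colMeans(cell)
  SS_G <- n_env * sum((m_seg - grand)^2)
  SS_E <- n_seg * sum((m_env - grand)^2)
  inter <- cell - outer(m_seg, rep(1, n_env)) -
    outer(rep(1, n_seg), m_env) + grand
  SS_GxE <- sum(inter^2)
  SS_total <- sum((cell - grand)^2)
  SS_resid <- max(0, SS_total - SS_G - SS_E - SS_GxE)
  structure(list(
    SS_G = SS_G, SS_E = SS_E, SS_GxE = SS_GxE, SS_resid = SS_resid,
    SS_total = SS_total,
    fraction_G = if (SS_total > 0) SS_G / SS_total else 0,
    fraction_E = if (SS_total > 0) SS_E / SS_total else 0,
    fraction_GxE = if (SS_total > 0) SS_GxE / SS_total else 0,
    grand_mean = grand,
    n_segregants = n_seg, n_environments = n_env,
    excluded_segregants = drop
  ), class = "varcomp")
}
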
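#' Conditional narrow-sense heritability by hub genotype
#'
#' Splits the panel by the genotype at a hub locus and, within each stratum,
#' fits the segregant mean growth jointly on the radial loci. The stratified
#' narrow-sense heritability is the adjusted r-squared of that additive model
#' (clamped to [0, 1]); a capacitating hub shows a large difference between
#' the two strata because one hub allele hides the radial allelic effects
#' while the other releases them. The per-radial-locus effect estimates from
#' the same stratified fits are returned as well.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param hub hub marker id.
#' @param radials radial marker ids (must not contain the hub).
#' @param environment environment label.
#' @param min_group minimum segregants per hub genotype group (default 30).
#' @return list of class `capacitation_stat`: `hub`, `environment`,
#'   `h2_allele0`, `h2_allele2`, `delta_h2` (allele-2 minus allele-0),
#'   `effects` (data frame with per-stratum radial estimates) and the group
#'   sizes.
#' @export
conditional_h2 <- function(geno, pheno, hub, radials, environment,
                           min_group = 30) {
  radials <- setdiff(as.character(radials), hub)
  if (length(radials) == 0L) stop("no radial loci supplied")
  .check_geno_loci(geno, c(hub, radials))
  al <- .segregant_means(geno, pheno, environment)
  gH <- al$G[, hub]
  sizes <- c(`0` = sum(gH == 0), `2` = sum(gH == 2))
  if (any(sizes < min_group)) {
    stop("hub genotype group too small (allele 0: ", sizes[1L],
         ", allele 2: ", sizes[2L], "; need >= ", min_group, ")")
  }
  fit_stratum <- function(allele) {
    keep <- gH == allele
    X <- cbind(`(Intercept)` = 1, al$G[keep, radials, drop = FALSE])
    fit <- .ols(X, al$y[keep])
    list(h2 = min(1, max(0, fit$adj_r2)),
         effects = data.frame(locus = radials, hub_allele = allele,
                              effect = unname(fit$coef[-1L]),
                              se = unname(fit$se[-1L]),
                              stringsAsFactors = FALSE))
  }
  s0 <- fit_stratum(0)
  s2 <- fit_stratum(2)
  structure(list(hub = hub, environment = environment,
                 h2_allele0 = s0$h2, h2_allele2 = s2$h2,
                 delta_h2 = s2$h2 - s0$h2,
                 effects = rbind(s0$effects, s2$effects),
                 n_allele0 = unname(sizes[1L]),
                 n_allele2 = unname(sizes[2L])),
            class = "capacitation_stat")
}

#' Multi-locus genotype-class by environment interaction test
#'
#' Treats the joint genotype at up to six loci as a single factor (up to 64
#' classes in a haploid biallelic cross) and tests, on the replicate-level
#' growth values, whether the class effects differ between environments:
#' full model = environment + class + class:environment, reduced model
#' without the interaction, compared by a Gaussian profiled likelihood-ratio
#' test. Genotype classes that are not observed are dropped and reported;
#' with all classes and cells observed the degrees of freedom are
#' `(classes - 1) * (environments - 1)` (computed as the design rank
#' difference, which also covers sparser layouts).
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table (replicate level).
#' @param loci marker ids defining the genotype classes (at most 6).
#' @param environments environments to include (default: all in `pheno`).
#' @return list (`LR`, `df`, `p`, `n_classes`, `dropped_classes`,
#'   `loglik_reduced`, `loglik_full`).
#' @export
genotype_class_env_lrt <- function(geno, pheno, loci, environments = NULL) {
  loci <- as.character(loci)
  if (length(loci) > 6L) stop("at most 6 loci are supported")
  .check_geno_loci(geno, loci)
  envs <- environments %||% .environments(pheno)
  if (length(envs) < 2L) stop("at least two environments are required")
  ph <- pheno[pheno$environment %in% envs &
                pheno$segregant %in% rownames(geno), , drop = FALSE]
  cls <- apply(geno[ph$segregant, loci, drop = FALSE], 1L, paste,
               collapse = "/")
  observed <- sort(unique(cls))
  if (length(observed) < 2L) stop("fewer than 2 observed genotype classes")
  all_classes <- apply(expand.grid(rep(list(c(0L, 2L)), length(loci))), 1L,
                       paste, collapse = "/")
  dropped <- setdiff(all_classes, observed)
  fE <- factor(ph$environment, levels = envs)
  fC <- factor(cls, levels = observed)
  Xr <- stats::model.matrix(~ fE + fC)
  Xf <- stats::model.matrix(~ fE + fC + fE:fC)
  yr <- ph$growth
  qr_r <- qr(Xr)
  qr_f <- qr(Xf)
  rss_r <- sum(qr.resid(qr_r, yr)^2)
  rss_f <- sum(qr.resid(qr_f, yr)^2)
  n <- length(yr)
  ll_r <- .gauss_loglik(rss_r, n)
  ll_f <- .gauss_loglik(rss_f, n)
  LR <- max(0, 2 * (ll_f - ll_r))
  df <- qr_f$rank - qr_r$rank
  list(LR = LR, df = df, p = stats::pchisq(LR, df, lower.tail = FALSE),
       n_classes = length(observed), dropped_classes = dropped,
       loglik_reduced = ll_r, loglik_full = ll_f)
}

#' Growth by count of growth-decreasing radial alleles, split by hub genotype
#'
#' Defines, per radial locus, the growth-decreasing allele from the sign of
#' its effect in the joint additive fit (hub + radials) in the chosen
#' environment: allele 2 if the per-copy effect is negative, allele 0
#' otherwise. Each segregant is scored by how many growth-decreasing radial
#' alleles it carries, and groups defined by (count, hub genotype) are
#' summarised. Under capacitation, mean growth declines with the count in the
#' released hub group but stays flat in the masked group.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param hub hub marker id.
#' @param radials radial marker ids.
#' @param environment environment label.
#' @return data frame (`n_decreasing`, `hub_allele`, `n`, `mean_growth`,
#'   `sd_growth`) with the effect signs as attribute `decreasing_allele`.
#' @export
decreasing_allele_profile <- function(geno, pheno, hub, radials,
                                      environment) {
  radials <- setdiff(as.character(radials), hub)
  .check_geno_loci(geno, c(hub, radials))
  al <- .segregant_means(geno, pheno, environment)
  X <- cbind(`(Intercept)` = 1, al$G[, c(hub, radials), drop = FALSE])
  fit <- .ols(X, al$y)
  eff <- fit$coef[radials]
  dec_allele <- ifelse(eff < 0, 2L, 0L)
  carry <- sweep(al$G[, radials, drop = FALSE], 2L, dec_allele, "==")
  counts <- rowSums(carry)
  gH <- al$G[, hub]
  grp <- split(al$y, list(n_decreasing = counts, hub_allele = gH), drop = TRUE)
  keys <- do.call(rbind, strsplit(names(grp), ".", fixed = TRUE))
  out <- data.frame(
    n_decreasing = as.integer(keys[, 1L]),
    hub_allele = as.integer(keys[, 2L]),
    n = vapply(grp, length, integer(1)),
    mean_growth = vapply(grp, mean, numeric(1)),
    sd_growth = vapply(grp, stats::sd, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$hub_allele, out$n_decreasing), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "decreasing_allele") <- dec_allele
  out
}
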
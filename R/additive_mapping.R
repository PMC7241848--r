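#' Marginal single-locus scan in one environment
#'
#' Per-marker simple regression of the segregant mean growth on the coded
#' genotype (0/2), giving per-allele-copy effect estimates and two-sided t
#' tests. Monomorphic markers are recorded with effect 0 and p = 1 and
#' flagged. This plays the role of the upstream per-environment QTL mapping
#' when the package is run on synthetic panels.
#'
#' @param geno genotype matrix.
#' @param pheno long-format phenotype table.
#' @param environment environment label to scan.
#' @return data frame (`locus`, `environment`, `effect`, `se`, `t`, `p`,
#'   `monomorphic`) with attribute `provenance = "scan"`.
#' @export
marginal_scan <- function(geno, pheno, environment) {
  al <- .segregant_means(geno, pheno, environment)
  y <- al$y
  G <- al$G
  n <- length(y)
  yc <- y - mean(y)
  gc <- sweep(G, 2, colMeans(G))
  sxx <- colSums(gc^2)
  sxy <- as.numeric(crossprod(gc, yc))
  mono <- sxx == 0
  beta <- ifelse(mono, 0, sxy / ifelse(mono, 1, sxx))
  rss <- sum(yc^2) - beta^2 * sxx
  sigma2 <- rss / (n - 2)
  se <- ifelse(mono, NA_real_, sqrt(sigma2 / ifelse(mono, 1, sxx)))
  tval <- ifelse(mono, 0, beta / se)
  pval <- ifelse(mono, 1,
                 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE))
  out <- data.frame(locus = colnames(G), environment = environment,
                    effect = beta, se = se, t = tval, p = pval,
                    monomorphic = mono, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "provenance") <- "scan"
  out
}

#' Collapse linked, correlated peaks to an independent locus set
#'
#' Peaks are clustered when they are BOTH within `max_dist_bp` on the same
#' chromosome AND in pairwise genotype r-squared above `min_r2` (single
#' linkage over the conjunction); each cluster is represented by its most
#' significant peak, ties broken by the leftmost genomic coordinate.
#'
#' @param peaks data frame with columns `locus` and `p` (e.g. pooled
#'   [marginal_scan()] rows, or an imported QTL table); if a locus appears in
#'   several environments its smallest p is used.
#' @param geno genotype matrix (r-squared is computed on coded genotypes
#'   across segregants).
#' @param map genetic map.
#' @param max_dist_bp physical distance threshold (default 20000).
#' @param min_r2 genotype r-squared threshold (default 0.9).
#' @return an object of class `locus_set`: list with `loci` (representative
#'   marker ids, map order), `clusters`, and the selection parameters.
#' @export
prune_loci <- function(peaks, geno, map, max_dist_bp = 20000, min_r2 = 0.9) {
  if (nrow(peaks) == 0L) stop("peaks table is empty")
  .check_geno_loci(geno, peaks$locus, "peak locus")
  pk <- stats::aggregate(p ~ locus, data = peaks, FUN = min)
  pk <- merge(pk, map, by.x = "locus", by.y = "marker")
  pk <- pk[order(pk$chrom, pk$pos_bp), , drop = FALSE]
  n <- nrow(pk)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (pk$chrom[j] != pk$chrom[i]) break
      if (pk$pos_bp[j] - pk$pos_bp[i] > max_dist_bp) break
      r2 <- stats::cor(geno[, pk$locus[i]], geno[, pk$locus[j]])^2
      if (!is.na(r2) && r2 > min_r2) {
        parent[find(j)] <- find(i)
      }
    }
  }
  cluster <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(seq_len(n), cluster), function(idx) {
    best <- idx[order(pk$p[idx], pk$pos_bp[idx])][1L]
    pk$locus[best]
  }, character(1))
  loci <- map$marker[map$marker %in% reps]
  structure(list(
    loci = loci,
    clusters = split(pk$locus, cluster),
    flags = NULL,
    params = list(max_dist_bp = max_dist_bp, min_r2 = min_r2)
  ), class = "locus_set")
}

#' Per-environment polygenic selection of jointly significant loci
#'
#' For each environment, all candidate loci are fitted jointly by least
#' squares on the segregant mean growth, and the per-locus t-test p-values
#' are subjected to Benjamini-Hochberg control at the stated false discovery
#' rate. Loci surviving in an environment are flagged there.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param candidates a `locus_set` or character vector of marker ids.
#' @param fdr false discovery rate (default 0.05).
#' @param environments environments to analyse (default: all in `pheno`).
#' @return the `locus_set` augmented with a logical `flags` matrix
#'   (loci x environments) and the `fdr` used.
#' @export
polygenic_select <- function(geno, pheno, candidates, fdr = 0.05,
                             environments = NULL) {
  loci <- if (inherits(candidates, "locus_set")) candidates$loci else
    as.character(candidates)
  .check_geno_loci(geno, loci)
  envs <- environments %||% .environments(pheno)
  flags <- matrix(FALSE, nrow = length(loci), ncol = length(envs),
                  dimnames = list(loci, envs))
  pmat <- flags
  storage.mode(pmat) <- "double"
  for (e in envs) {
    tab <- estimate_effects(geno, pheno, loci, environments = e)
    padj <- stats::p.adjust(tab$p, method = "BH")
    flags[tab$locus, e] <- padj < fdr
    pmat[tab$locus, e] <- tab$p
  }
  out <- if (inherits(candidates, "locus_set")) candidates else
    structure(list(loci = loci, clusters = NULL, params = list()),
              class = "locus_set")
  out$flags <- flags
  out$p <- pmat
  out$fdr <- fdr
  out
}

#' Joint additive effect estimation per environment
#'
#' Fits the segregant mean growth in each environment on all loci
#' simultaneously (ordinary least squares with an intercept). With the 0/2
#' genotype coding the estimates are additive effects per allele copy.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param loci a `locus_set` or character vector of marker ids.
#' @param environments environments to fit (default: all in `pheno`); each
#'   environment is fitted independently.
#' @param fdr optional; if given, a per-environment Benjamini-Hochberg
#'   `significant` flag at this rate is added.
#' @return data frame (`locus`, `environment`, `effect`, `se`, `t`, `p`
#'   and optionally `significant`).
#' @export
estimate_effects <- function(geno, pheno, loci, environments = NULL,
                             fdr = NULL) {
  ids <- if (inherits(loci, "locus_set")) loci$loci else as.character(loci)
  .check_geno_loci(geno, ids)
  envs <- environments %||% .environments(pheno)
  out <- lapply(envs, function(e) {
    al <- .segregant_means(geno, pheno, e)
    if (length(al$y) <= length(ids) + 1L) {
      stop("fewer segregants (", length(al$y), ") than parameters (",
           length(ids) + 1L, ") in environment ", e)
    }
    X <- cbind(`(Intercept)` = 1, al$G[, ids, drop = FALSE])
    fit <- .ols(X, al$y)
    data.frame(locus = ids, environment = e,
               effect = unname(fit$coef[-1L]), se = unname(fit$se[-1L]),
               t = unname(fit$t[-1L]), p = unname(fit$p[-1L]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  if (!is.null(fdr)) {
    tab$significant <- stats::ave(tab$p, tab$environment, FUN = function(p)
      as.numeric(stats::p.adjust(p, "BH") < fdr)) > 0
    attr(tab, "fdr") <- fdr
  }
  tab
}

#' Likelihood-ratio test for a group of loci beyond the significant set
#'
#' Compares, on the segregant means of one environment, the joint additive
#' model containing only that environment's individually significant loci
#' against the model that adds the remaining loci of the across-environment
#' set. The statistic is the Gaussian profiled-likelihood ratio
#' `LR = n log(RSS_reduced / RSS_full)` referred to a chi-squared
#' distribution with as many degrees of freedom as added loci. A significant
#' test means the individually non-significant loci still contribute
#' polygenically to growth in this environment.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param sig_loci marker ids individually significant in `environment`.
#' @param other_loci marker ids of the remaining set members.
#' @param environment environment label.
#' @return list (`LR`, `df`, `p`, `loglik_reduced`, `loglik_full`).
#' @export
group_lrt <- function(geno, pheno, sig_loci, other_loci, environment) {
  sig_loci <- as.character(sig_loci)
  other_loci <- setdiff(as.character(other_loci), sig_loci)
  .check_geno_loci(geno, c(sig_loci, other_loci))
  al <- .segregant_means(geno, pheno, environment)
  X1 <- cbind(`(Intercept)` = 1, al$G[, sig_loci, drop = FALSE])
  if (length(other_loci) == 0L) {
    fit1 <- .ols(X1, al$y)
    return(list(LR = 0, df = 0L, p = 1,
                loglik_reduced = fit1$loglik, loglik_full = fit1$loglik))
  }
  X2 <- cbind(X1, al$G[, other_loci, drop = FALSE])
  fit1 <- .ols(X1, al$y)
  fit2 <- .ols(X2, al$y)
  LR <- max(0, 2 * (fit2$loglik - fit1$loglik))
  df <- length(other_loci)
  list(LR = LR, df = df, p = stats::pchisq(LR, df, lower.tail = FALSE),
       loglik_reduced = fit1$loglik, loglik_full = fit2$loglik)
}
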
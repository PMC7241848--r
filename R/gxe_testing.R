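# residuals of x against the column space of a (possibly LAPACK) qr object;
# qr.resid() itself does not accept LAPACK factorisations
.qr_resid <- function(qrobj, x) {
  qty <- qr.qty(qrobj, x)
  if (is.matrix(qty)) {
    qty[seq_len(qrobj$rank), ] <- 0
  } else {
    qty[seq_len(qrobj$rank)] <- 0
  }
  qr.qy(qrobj, qty)
}

# Shared machinery for the locus-by-environment LRTs: the reduced model
# (environment main effects + all loci additive) is identical for every
# focal locus, so it is factorised once and each interaction block is
# tested on the residualised scale (Frisch-Waugh), which is numerically
# identical to refitting the full model.
.gxe_machine <- function(geno, pheno, ids, environments = NULL) {
  .check_geno_loci(geno, ids)
  envs <- environments %||% .environments(pheno)
  if (length(envs) < 2L) stop("at least two environments are required")
  ph <- pheno[pheno$environment %in% envs &
                pheno$segregant %in% rownames(geno), , drop = FALSE]
  E <- factor(ph$environment, levels = envs)
  Edum <- stats::model.matrix(~E)[, -1L, drop = FALSE]
  G <- geno[ph$segregant, ids, drop = FALSE]
  X4 <- cbind(`(Intercept)` = 1, Edum, G)
  qr4 <- qr(X4, LAPACK = TRUE)
  if (qr4$rank < ncol(X4)) {
    stop("reduced G-by-E design is rank deficient; ",
         "prune collinear loci first")
  }
  r4 <- .qr_resid(qr4, ph$growth)
  rss4 <- sum(r4^2)
  n <- nrow(ph)
  list(ph = ph, envs = envs, Edum = Edum, G = G, qr4 = qr4, r4 = r4,
       rss4 = rss4, n = n, loglik4 = .gauss_loglik(rss4, n))
}

.gxe_test_one <- function(m, focal) {
  classes <- tapply(m$G[, focal], m$ph$environment,
                    function(g) length(unique(g)))
  if (any(classes < 2L)) {
    stop("interaction inestimable: focal locus ", focal,
         " has a single genotype class in environment(s) ",
         paste(names(classes)[classes < 2L], collapse = ", "))
  }
  Z <- m$Edum * m$G[, focal]
  Zt <- .qr_resid(m$qr4, Z)
  qz <- qr(Zt)
  rss5 <- sum(qr.resid(qz, m$r4)^2)
  LR <- max(0, m$n * log(m$rss4 / rss5))
  df <- length(m$envs) - 1L
  data.frame(locus = focal, LR = LR, df = df,
             p = stats::pchisq(LR, df, lower.tail = FALSE),
             loglik_reduced = m$loglik4,
             loglik_full = .gauss_loglik(rss5, m$n),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test for a locus-by-environment interaction
#'
#' Fits, on the replicate-level growth values, a full model containing the
#' environment main effects, the additive effects of all mapped loci
#' (polygenicity is accounted for by fitting them simultaneously) and an
#' interaction between the focal locus and the environment, against the
#' reduced model without the interaction. The Gaussian profiled
#' likelihood-ratio statistic is referred to a chi-squared distribution with
#' `(number of environments - 1)` degrees of freedom.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table (replicate level).
#' @param loci a `locus_set` or character vector: all mapped loci to adjust
#'   for (the focal locus is added if absent).
#' @param focal the focal marker id whose G-by-E interaction is tested.
#' @param environments environments to include (default: all in `pheno`).
#' @return one-row data frame (`locus`, `LR`, `df`, `p`, `loglik_reduced`,
#'   `loglik_full`).
#' @export
qtl_by_env_lrt <- function(geno, pheno, loci, focal, environments = NULL) {
  ids <- if (inherits(loci, "locus_set")) loci$loci else as.character(loci)
  if (!focal %in% ids) ids <- c(ids, focal)
  m <- .gxe_machine(geno, pheno, ids, environments)
  .gxe_test_one(m, focal)
}

#' Test every locus of a set for G-by-E interaction
#'
#' Runs the locus-by-environment LRT of [qtl_by_env_lrt()] for each locus in
#' turn (sharing the common reduced-model factorisation across loci) and
#' applies [correct_gxe()] to the collected results.
#'
#' @inheritParams qtl_by_env_lrt
#' @param alpha family-wise error rate for the corrected flags.
#' @return data frame of per-locus results with adjusted p-values and flags.
#' @export
test_gxe_all <- function(geno, pheno, loci, environments = NULL,
                         alpha = 0.05) {
  ids <- if (inherits(loci, "locus_set")) loci$loci else as.character(loci)
  m <- .gxe_machine(geno, pheno, ids, environments)
  res <- do.call(rbind, lapply(ids, function(l) .gxe_test_one(m, l)))
  correct_gxe(res, alpha = alpha)
}

#' Multiple-testing correction for G-by-E tests
#'
#' Bonferroni correction over the number of tested loci, controlling the
#' family-wise error rate.
#'
#' @param results data frame of [qtl_by_env_lrt()] rows.
#' @param alpha family-wise error rate (default 0.05).
#' @param method correction method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return `results` with columns `p_adjusted` and `significant` added.
#' @export
correct_gxe <- function(results, alpha = 0.05, method = "bonferroni") {
  if (nrow(results) < 1L) stop("no G-by-E results to correct")
  results$p_adjusted <- stats::p.adjust(results$p, method = method)
  results$significant <- results$p_adjusted < alpha
  attr(results, "alpha") <- alpha
  attr(results, "method") <- method
  results
}
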
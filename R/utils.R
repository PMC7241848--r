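`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian profiled log-likelihood of a least-squares fit
.gauss_loglik <- function(rss, n) {
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

# Least-squares fit on an explicit design matrix. Returns coefficients with
# standard errors and t tests, the residual sum of squares and the rank.
# Stops (naming the aliased columns) if the design is rank deficient and
# allow_aliased is FALSE; otherwise drops aliased columns with a warning.
.ols <- function(X, y, allow_aliased = FALSE) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    if (!allow_aliased) {
      stop("design matrix is rank deficient; collinear columns: ",
           paste(aliased, collapse = ", "))
    }
    warning("dropping aliased columns: ", paste(aliased, collapse = ", "))
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    qrx <- qr(X)
  }
  n <- length(y)
  p <- qrx$rank
  coefs <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  rss <- sum(res^2)
  sigma2 <- rss / max(n - p, 1)
  XtXinv_diag <- diag(chol2inv(qr.R(qrx)))[order(qrx$pivot)]
  se <- sqrt(sigma2 * XtXinv_diag)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  adj_r2 <- if (n - p > 0 && tss > 0) 1 - (1 - r2) * (n - 1) / (n - p) else r2
  list(coef = coefs, se = se, t = tval, p = pval, rss = rss, n = n,
       rank = p, r2 = r2, adj_r2 = adj_r2,
       loglik = .gauss_loglik(rss, n))
}

# Per-segregant replicate means for one environment, aligned with the
# genotype matrix rows present in the phenotype table.
.segregant_means <- function(geno, pheno, environment) {
  ph <- pheno[pheno$environment == environment, , drop = FALSE]
  if (nrow(ph) == 0L) {
    stop("environment '", environment, "' not present in the phenotype table")
  }
  m <- tapply(ph$growth, ph$segregant, mean)
  ids <- intersect(rownames(geno), names(m))
  if (length(ids) == 0L) {
    stop("no segregants shared between genotypes and phenotypes")
  }
  list(y = as.numeric(m[ids]), ids = ids,
       G = geno[ids, , drop = FALSE])
}

.environments <- function(pheno) sort(unique(as.character(pheno$environment)))

.check_geno_loci <- function(geno, loci, what = "locus") {
  missing <- setdiff(loci, colnames(geno))
  if (length(missing) > 0L) {
    stop(what, " not present in the genotype matrix: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# Canonical unordered pair key
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
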
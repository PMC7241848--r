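test_that("a strong planted locus attains the genome-wide minimum p", {
  map <- make_genetic_map(5, 10, 20)
  causal <- map$marker[25L]
  arch <- constant_additive_arch("e1", causal, 0.5, residual_sd = 1,
                                 replicates = 1, map = map)
  g <- simulate_genotypes(2000, map, seed = 61)
  p <- simulate_phenotypes(g, arch, seed = 62)
  scan <- marginal_scan(g, p, "e1")
  expect_equal(scan$locus[which.min(scan$p)], causal)
})

test_that("a constant phenotype scans to all-zero effects and monomorphic markers are flagged", {
  map <- unlinked_map(5)
  g <- simulate_genotypes(50, map, seed = 63)
  g[, 3L] <- 0L  # monomorphic
  ph <- data.frame(segregant = rownames(g), environment = "e1",
                   replicate = 1L, growth = 1)
  scan <- marginal_scan(g, ph, "e1")
  expect_true(all(scan$effect == 0))
  expect_true(scan$monomorphic[3L])
  expect_equal(scan$p[3L], 1)
})

test_that("the null rejection rate of the marginal scan is calibrated", {
  map <- unlinked_map(100)
  set.seed(64)
  hits <- 0L
  n_tests <- 0L
  for (s in 1:40) {
    g <- simulate_genotypes(200, map)
    ph <- data.frame(segregant = rownames(g), environment = "e1",
                     replicate = 1L, growth = rnorm(200))
    scan <- marginal_scan(g, ph, "e1")
    hits <- hits + sum(scan$p < 0.05)
    n_tests <- n_tests + nrow(scan)
  }
  expect_lt(abs(hits / n_tests - 0.05), binom_ci_halfwidth(0.05, n_tests) * 1.5)
})

test_that("pruning applies the distance AND r-squared conjunction", {
  # three markers on one chromosome: a/b tightly linked and close,
  # c close to b but recombinationally distant is impossible physically,
  # so build the cases with two maps
  map1 <- data.frame(marker = c("a", "b"), chrom = "chr1",
                     pos_bp = c(1000L, 6000L), pos_cM = c(0, 0.05))
  g1 <- simulate_genotypes(500, map1, seed = 65)
  peaks1 <- data.frame(locus = c("a", "b"), p = c(1e-10, 1e-4))
  ls1 <- prune_loci(peaks1, g1, map1)
  expect_identical(ls1$loci, "a")  # r2 ~ 1, 5 kb apart: collapsed to min p

  # same 5 kb distance but low linkage (50 cM): both retained
  map2 <- data.frame(marker = c("a", "b"), chrom = "chr1",
                     pos_bp = c(1000L, 6000L), pos_cM = c(0, 50))
  g2 <- simulate_genotypes(500, map2, seed = 66)
  ls2 <- prune_loci(peaks1, g2, map2)
  expect_setequal(ls2$loci, c("a", "b"))

  # tight linkage but 100 kb apart: both retained
  map3 <- data.frame(marker = c("a", "b"), chrom = "chr1",
                     pos_bp = c(1000L, 101000L), pos_cM = c(0, 0.05))
  g3 <- simulate_genotypes(500, map3, seed = 67)
  ls3 <- prune_loci(peaks1, g3, map3)
  expect_setequal(ls3$loci, c("a", "b"))

  # a single peak is returned unchanged
  ls4 <- prune_loci(peaks1[1L, ], g1, map1)
  expect_identical(ls4$loci, "a")
})

test_that("pruned sets contain no close, correlated locus pairs", {
  map <- make_genetic_map(n_chrom = 3, markers_per_chrom = 30,
                          spacing_cM = 2, bp_per_cM = 2500)
  g <- simulate_genotypes(400, map, seed = 68)
  set.seed(69)
  for (rep in 1:5) {
    loci <- sample(map$marker, 25)
    peaks <- data.frame(locus = loci, p = runif(25, 1e-12, 1e-3))
    ls <- prune_loci(peaks, g, map)
    kept <- map[match(ls$loci, map$marker), ]
    for (i in seq_len(nrow(kept) - 1L)) {
      for (j in (i + 1L):nrow(kept)) {
        if (kept$chrom[i] != kept$chrom[j]) next
        close <- abs(kept$pos_bp[i] - kept$pos_bp[j]) <= 20000
        r2 <- cor(g[, kept$marker[i]], g[, kept$marker[j]])^2
        expect_false(close && r2 > 0.9)
      }
    }
  }
})

test_that("polygenic selection flags a huge effect and is monotone in the FDR", {
  map <- unlinked_map(10)
  loci <- map$marker
  arch <- constant_additive_arch("e1", loci[1:3], c(1, 0.12, 0.08),
                                 residual_sd = 1, replicates = 1, map = map)
  g <- simulate_genotypes(600, map, seed = 71)
  p <- simulate_phenotypes(g, arch, seed = 72)
  sel05 <- polygenic_select(g, p, loci, fdr = 0.05)
  sel01 <- polygenic_select(g, p, loci, fdr = 0.01)
  expect_true(sel05$flags[loci[1L], "e1"])
  flagged01 <- rownames(sel01$flags)[sel01$flags[, "e1"]]
  flagged05 <- rownames(sel05$flags)[sel05$flags[, "e1"]]
  expect_true(all(flagged01 %in% flagged05))
})

test_that("polygenic selection rarely flags anything on pure noise", {
  map <- unlinked_map(8)
  set.seed(73)
  clean <- 0L
  n_sim <- 40
  for (s in seq_len(n_sim)) {
    g <- simulate_genotypes(300, map)
    ph <- data.frame(segregant = rownames(g), environment = "e1",
                     replicate = 1L, growth = rnorm(300))
    sel <- polygenic_select(g, ph, map$marker, fdr = 0.05)
    clean <- clean + (sum(sel$flags) == 0L)
  }
  expect_gte(clean / n_sim, 0.9)
})

test_that("joint estimation is exact without noise and unbiased with noise", {
  map <- unlinked_map(6)
  arch <- constant_additive_arch("e1", map$marker[1L], 0.3,
                                 residual_sd = 1e-12, replicates = 1,
                                 map = map)
  g <- simulate_genotypes(200, map, seed = 74)
  p <- simulate_phenotypes(g, arch, seed = 75)
  eff <- estimate_effects(g, p, map$marker[1L])
  expect_equal(eff$effect, 0.3, tolerance = 1e-10)

  # sampling behaviour: mean near truth, model SE near empirical SE
  set.seed(76)
  est <- se <- numeric(60)
  arch2 <- constant_additive_arch("e1", map$marker[1L], 0.3,
                                  residual_sd = 1, replicates = 1, map = map)
  for (s in 1:60) {
    g2 <- simulate_genotypes(1000, map)
    p2 <- simulate_phenotypes(g2, arch2)
    e2 <- estimate_effects(g2, p2, map$marker[1L])
    est[s] <- e2$effect
    se[s] <- e2$se
  }
  expect_lt(abs(mean(est) - 0.3), 0.02)
  expect_lt(abs(sd(est) / mean(se) - 1), 0.3)
})

test_that("joint fits agree with marginal fits for orthogonal loci and beat them under collinearity", {
  # balanced factorial design: exactly orthogonal 0/2 columns
  g <- as.matrix(expand.grid(a = c(0L, 2L), b = c(0L, 2L)))
  g <- g[rep(1:4, each = 25), ]
  rownames(g) <- sprintf("s%03d", 1:100)
  set.seed(77)
  y <- 0.4 * g[, "a"] - 0.2 * g[, "b"] + rnorm(100, 0, 0.5)
  ph <- data.frame(segregant = rownames(g), environment = "e1",
                   replicate = 1L, growth = y)
  joint <- estimate_effects(g, ph, c("a", "b"))
  marg <- marginal_scan(g, ph, "e1")
  expect_equal(joint$effect, marg$effect, tolerance = 1e-8)

  # linked pair, only one causal: the joint fit assigns the effect to the
  # causal locus on average while the marginal fit inflates its neighbour
  map <- data.frame(marker = c("c1", "c2"), chrom = "chr1",
                    pos_bp = c(1L, 2L), pos_cM = c(0, 17.83))
  # corr = 1 - 2r ~ 0.707 so r2 ~ 0.5
  set.seed(78)
  jnull <- mnull <- numeric(50)
  for (s in 1:50) {
    gl <- simulate_genotypes(1000, map)
    yl <- 0.3 * gl[, "c1"] + rnorm(1000)
    phl <- data.frame(segregant = rownames(gl), environment = "e1",
                      replicate = 1L, growth = yl)
    jnull[s] <- estimate_effects(gl, phl, c("c1", "c2"))$effect[2L]
    mnull[s] <- marginal_scan(gl, phl, "e1")$effect[2L]
  }
  expect_lt(abs(mean(jnull)), 0.02)
  expect_gt(mean(mnull), 0.15)
})

test_that("the group LRT matches lmtest on real fits and handles the empty group", {
  map <- unlinked_map(8)
  loci <- map$marker
  arch <- constant_additive_arch("e1", loci[1:2], c(0.3, 0.2),
                                 residual_sd = 1, replicates = 1, map = map)
  g <- simulate_genotypes(400, map, seed = 79)
  p <- simulate_phenotypes(g, arch, seed = 80)
  res <- group_lrt(g, p, loci[1:2], loci[3:5], "e1")
  expect_equal(res$df, 3L)

  # independent route: lm + lmtest::lrtest on the same segregant means
  m <- tapply(p$growth, p$segregant, mean)[rownames(g)]
  d <- data.frame(y = as.numeric(m), g[, loci[1:5]])
  f1 <- lm(y ~ ., data = d[, 1:3])
  f2 <- lm(y ~ ., data = d)
  lt <- lmtest::lrtest(f1, f2)
  expect_equal(res$LR, lt$Chisq[2L], tolerance = 1e-8)
  expect_equal(res$p, lt$`Pr(>Chisq)`[2L], tolerance = 1e-8)

  empty <- group_lrt(g, p, loci[1:2], character(), "e1")
  expect_equal(empty[c("LR", "df", "p")], list(LR = 0, df = 0L, p = 1))
})

test_that("the group LRT detects a planted polygenic contribution", {
  map <- unlinked_map(8)
  loci <- map$marker
  arch <- constant_additive_arch("e1", loci[1:4],
                                 c(0.4, 0.3, 0.3, 0.3),
                                 residual_sd = 1, replicates = 1, map = map)
  g <- simulate_genotypes(4000, map, seed = 81)
  p <- simulate_phenotypes(g, arch, seed = 82)
  res <- group_lrt(g, p, loci[1L], loci[2:4], "e1")
  expect_lt(res$p, 1e-6)
})

test_that("rank-deficient joint designs fail naming the collinear loci", {
  map <- data.frame(marker = c("a", "b"), chrom = "chr1",
                    pos_bp = c(1L, 2L), pos_cM = c(0, 0))
  g <- simulate_genotypes(100, map, seed = 83)  # identical columns
  ph <- data.frame(segregant = rownames(g), environment = "e1",
                   replicate = 1L, growth = rnorm(100))
  expect_error(estimate_effects(g, ph, c("a", "b")), "collinear.*b")
})
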
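test_that("a planted interaction is detected and an additive pair is not", {
  map <- unlinked_map(4)
  envs <- "e1"
  g <- simulate_genotypes(4000, map, seed = 101)
  arch <- sim_architecture(envs,
    epistatic = data.frame(locusA = map$marker[1L], locusB = map$marker[2L],
                           environment = "e1", effect = 0.4),
    residual_sd = 1, replicates = 1, map = map)
  p <- simulate_phenotypes(g, arch, seed = 102)
  hit <- pairwise_lrt(g, p, map$marker[1:2], "e1")
  expect_lt(hit$p, 1e-4)

  arch0 <- constant_additive_arch("e1", map$marker[1:2], c(0.4, 0.3),
                                  residual_sd = 1e-9, replicates = 1,
                                  map = map)
  p0 <- simulate_phenotypes(g, arch0, seed = 103)
  null <- pairwise_lrt(g, p0, map$marker[1:2], "e1")
  expect_lt(null$LR, qchisq(0.999, 1))
})

test_that("an empty two-locus genotype class makes the record inestimable", {
  g <- cbind(a = rep(c(0L, 2L), each = 50), b = rep(c(0L, 2L), each = 50))
  rownames(g) <- sprintf("s%03d", 1:100)
  ph <- data.frame(segregant = rownames(g), environment = "e1",
                   replicate = 1L, growth = rnorm(100))
  rec <- pairwise_lrt(g, ph, c("a", "b"), "e1")
  expect_false(rec$estimable)
  expect_true(is.na(rec$p))
})

test_that("the lenient re-test threshold corrects for the number of discovered pairs", {
  map <- unlinked_map(6)
  g <- simulate_genotypes(300, map, seed = 104)
  arch <- constant_additive_arch(c("e1", "e2"), map$marker[1L], 0.2,
                                 residual_sd = 1, replicates = 1, map = map)
  p <- simulate_phenotypes(g, arch, seed = 105)
  seeds2 <- data.frame(locusA = map$marker[c(1, 3)],
                       locusB = map$marker[c(2, 4)],
                       environment = "e1")
  rec <- retest_across_envs(g, p, seeds2)
  expect_equal(attr(rec, "threshold"), 0.05 / 2)
  expect_equal(nrow(rec), 4L)  # 2 pairs x 2 environments
  # discovery records stay active whatever their re-test p
  expect_true(all(rec$active[rec$discovery]))

  single <- retest_across_envs(g, p, seeds2[1L, ])
  expect_equal(attr(single, "threshold"), 0.05)

  # the paper-scale arithmetic: 212 discovered pairs
  expect_equal(0.05 / 212, 2.358491e-4, tolerance = 1e-6)

  # per-environment correction can only deactivate edges
  rec_strict <- retest_across_envs(g, p, seeds2, correct_per_env = TRUE)
  expect_lte(sum(rec_strict$active), sum(rec$active))
  expect_true(all(rec$active[rec_strict$active]))
})

test_that("activity flags recover an interaction active in two of three environments", {
  map <- unlinked_map(4)
  envs <- sprintf("e%d", 1:3)
  epi <- data.frame(locusA = map$marker[1L], locusB = map$marker[2L],
                    environment = envs, effect = c(0.5, 0.5, 0))
  arch <- sim_architecture(envs, epistatic = epi, residual_sd = 1,
                           replicates = 1, map = map)
  g <- simulate_genotypes(4000, map, seed = 106)
  p <- simulate_phenotypes(g, arch, seed = 107)
  rec <- retest_across_envs(g, p, data.frame(locusA = map$marker[1L],
                                             locusB = map$marker[2L],
                                             environment = "e1"))
  expect_identical(sort(rec$environment[rec$active]), c("e1", "e2"))
})

test_that("the multigraph assembles nodes, edges and interactor counts correctly", {
  recs <- make_records(list(c("A", "B"), c("B", "C")), c("e1", "e2"))
  net <- build_network(recs)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(igraph::ecount(net$graph), 2)
  expect_equal(net$interactor_counts["B", "e1"], 1L)
  expect_equal(net$interactor_counts["B", "e2"], 1L)
  expect_equal(unname(net$n_envs_epistatic["B"]), 2L)
  expect_equal(net$edge_env_counts$n_envs_active, c(1L, 1L))

  empty <- build_network(make_records(list(c("A", "B")), "e1",
                                      active = FALSE))
  expect_length(empty$nodes, 0)
  expect_length(find_hubs(empty), 0)
})

test_that("interactor counts are invariant to record order and endpoint swaps", {
  pairs <- list(c("H", "r1"), c("H", "r2"), c("H", "r3"), c("r1", "r2"))
  recs <- make_records(pairs, rep("e1", 4))
  set.seed(1)
  swapped <- recs[sample(nrow(recs)), ]
  tmp <- swapped$locusA
  swapped$locusA <- swapped$locusB
  swapped$locusB <- tmp
  n1 <- build_network(recs)
  n2 <- build_network(swapped)
  expect_equal(n2$interactor_counts[rownames(n1$interactor_counts), ,
                                    drop = FALSE],
               n1$interactor_counts)
})

test_that("hub detection uses a strict per-environment threshold", {
  star5 <- make_records(lapply(paste0("r", 1:5), function(r) c("H", r)),
                        rep("e1", 5))
  expect_identical(find_hubs(build_network(star5)), "H")

  star4 <- make_records(lapply(paste0("r", 1:4), function(r) c("H", r)),
                        rep("e1", 4))
  expect_length(find_hubs(build_network(star4)), 0)

  # 2 + 3 partners split over two environments never reach 5 in one
  split23 <- make_records(lapply(paste0("r", 1:5), function(r) c("H", r)),
                          c("e1", "e1", "e2", "e2", "e2"))
  expect_length(find_hubs(build_network(split23)), 0)
})

test_that("hub activity profiles use the most activated environment as reference", {
  pairs <- c(lapply(paste0("r", 1:5), function(r) c("H", r)),
             list(c("H", "r1"), c("H", "r2")))
  recs <- make_records(pairs, c(rep("e1", 5), "e2", "e2"))
  recs <- rbind(recs, make_records(list(c("H", "r1")), "e3",
                                   active = FALSE))
  net <- build_network(recs)
  additive <- data.frame(locus = c("r1", "r2", "r3"),
                         environment = c("e2", "e2", "e1"),
                         significant = TRUE)
  prof <- hub_activity_profile(net, additive, "H")
  expect_equal(prof$reference_env, "e1")
  expect_setequal(prof$interactors, paste0("r", 1:5))
  expect_equal(unname(prof$active_fraction["e1"]), 1)     # by construction
  expect_equal(unname(prof$active_fraction["e2"]), 2 / 5)
  expect_equal(unname(prof$active_fraction["e3"]), 0)
  expect_equal(unname(prof$additive_fraction["e2"]), 2 / 5)
  expect_equal(unname(prof$additive_fraction["e1"]), 1 / 5)
})

test_that("network fits rank hubs by their contribution per environment", {
  map <- unlinked_map(12)
  envs <- c("e1", "e2")
  hubA <- map$marker[1L]; radA <- map$marker[2:6]
  hubB <- map$marker[7L]; radB <- map$marker[8:12]
  arch <- capacitor_arch(envs, hubA, radA, effect = 0.4,
                         active_envs = "e1", map = map)
  g <- simulate_genotypes(2000, map, seed = 108)
  p <- simulate_phenotypes(g, arch, seed = 109)
  recs <- rbind(
    make_records(lapply(radA, function(r) c(hubA, r)), rep("e1", 5)),
    make_records(lapply(radB, function(r) c(hubB, r)), rep("e1", 5)))
  net <- build_network(recs)
  fits <- network_fit_rank(net, g, p)
  expect_true(all(tapply(fits$rank, fits$environment, function(r)
    setequal(r, seq_along(r)))))
  e1 <- fits[fits$environment == "e1", ]
  expect_equal(e1$hub[e1$rank == 1], hubA)  # the planted network fits best
  # a network of null loci explains essentially nothing
  expect_lt(abs(e1$adj_r2[e1$hub == hubB]), 0.01)
})

test_that("network summaries count environments per locus and per edge", {
  recs <- make_records(list(c("A", "B"), c("B", "C"), c("A", "B")),
                       c("e1", "e2", "e2"))
  net <- build_network(recs)
  s <- summarize_network(net)
  expect_equal(s$locus_epistatic_envs$n_envs[
    s$locus_epistatic_envs$locus == "B"], 2L)
  ee <- s$edge_env_counts
  expect_equal(ee$n_envs_active[ee$locusA == "A" & ee$locusB == "B"], 2L)
})

test_that("the variance-explained fraction stays within [0, 1]", {
  map <- unlinked_map(8)
  envs <- c("e1", "e2")
  arch <- constant_additive_arch(envs, map$marker[1:4], rep(0.3, 4),
                                 residual_sd = 1, replicates = 2, map = map)
  g <- simulate_genotypes(800, map, seed = 110)
  p <- simulate_phenotypes(g, arch, seed = 111)
  recs <- make_records(list(c(map$marker[1L], map$marker[2L])), "e1")
  net <- build_network(recs)
  s <- summarize_network(net, geno = g, pheno = p, full_loci = map$marker[1:4])
  ve <- s$variance_explained
  expect_true(all(ve$fraction >= 0 & ve$fraction <= 1, na.rm = TRUE))
  expect_true(all(ve$adj_r2_network >= 0))
})
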
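#' Likelihood-ratio test for one pairwise epistatic interaction
#'
#' On the segregant mean growth of one environment, compares the model with
#' both additive terms and their product interaction against the purely
#' additive model (chi-squared, 1 df). If one of the four two-locus genotype
#' classes is empty the interaction is inestimable and the record is flagged.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param pair character vector of two marker ids.
#' @param environment environment label.
#' @return one-row data frame (`locusA`, `locusB`, `environment`, `LR`, `p`,
#'   `estimable`).
#' @export
pairwise_lrt <- function(geno, pheno, pair, environment) {
  stopifnot(length(pair) == 2L, pair[1L] != pair[2L])
  .check_geno_loci(geno, pair)
  al <- .segregant_means(geno, pheno, environment)
  gA <- al$G[, pair[1L]]
  gB <- al$G[, pair[2L]]
  n_classes <- nrow(unique(cbind(gA, gB)))
  if (n_classes < 4L) {
    return(data.frame(locusA = pair[1L], locusB = pair[2L],
                      environment = environment, LR = NA_real_, p = NA_real_,
                      estimable = FALSE, stringsAsFactors = FALSE))
  }
  X0 <- cbind(`(Intercept)` = 1, gA = gA, gB = gB)
  X1 <- cbind(X0, `gA:gB` = gA * gB)
  fit0 <- .ols(X0, al$y)
  fit1 <- .ols(X1, al$y)
  LR <- max(0, 2 * (fit1$loglik - fit0$loglik))
  data.frame(locusA = pair[1L], locusB = pair[2L], environment = environment,
             LR = LR, p = stats::pchisq(LR, 1L, lower.tail = FALSE),
             estimable = TRUE, stringsAsFactors = FALSE)
}

#' Re-test discovered interaction pairs in every environment
#'
#' Each pair discovered in some environment is re-tested in all environments
#' under a lenient threshold that corrects only for the total number of
#' distinct pairs discovered across all environments (`alpha / N_pairs`; with
#' `correct_per_env = TRUE`, `alpha / (N_pairs * N_envs)` instead). A
#' (pair, environment) record is active if it is a discovery record or if its
#' re-test p-value falls below the lenient threshold. Records inestimable in
#' an environment (an empty two-locus genotype class) count as inactive.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param seed_pairs data frame (`locusA`, `locusB`, `environment`) of
#'   discovered interactions with their discovery environment.
#' @param environments environments to test in (default: all in `pheno`).
#' @param alpha base significance level (default 0.05).
#' @param correct_per_env also correct for the number of environments.
#' @return data frame of interaction records (`locusA`, `locusB`,
#'   `environment`, `LR`, `p`, `estimable`, `discovery`, `active`), with the
#'   lenient threshold as attribute `threshold`.
#' @export
retest_across_envs <- function(geno, pheno, seed_pairs, environments = NULL,
                               alpha = 0.05, correct_per_env = FALSE) {
  if (nrow(seed_pairs) == 0L) stop("seed_pairs is empty")
  envs <- environments %||% .environments(pheno)
  key <- .pair_key(seed_pairs$locusA, seed_pairs$locusB)
  pairs <- seed_pairs[!duplicated(key), c("locusA", "locusB"), drop = FALSE]
  n_pairs <- nrow(pairs)
  threshold <- alpha / n_pairs / (if (correct_per_env) length(envs) else 1)
  disc_key <- paste(key, seed_pairs$environment)
  recs <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    do.call(rbind, lapply(envs, function(e)
      pairwise_lrt(geno, pheno, c(pairs$locusA[i], pairs$locusB[i]), e)))
  }))
  recs$discovery <- paste(.pair_key(recs$locusA, recs$locusB),
                          recs$environment) %in% disc_key
  recs$active <- recs$discovery |
    (recs$estimable & !is.na(recs$p) & recs$p < threshold)
  attr(recs, "threshold") <- threshold
  attr(recs, "n_pairs") <- n_pairs
  rownames(recs) <- NULL
  recs
}

#' Assemble the across-environment epistatic multigraph
#'
#' Nodes are the loci appearing in at least one active interaction record;
#' each active (pair, environment) record is one undirected edge labelled by
#' its environment, so a pair active in several environments carries multiple
#' parallel edges. Per-node interactor counts (distinct partners with an
#' active edge, per environment) and per-edge environment counts are
#' precomputed.
#'
#' @param records interaction records (e.g. from [retest_across_envs()] or
#'   [read_interactions()]); must have columns `locusA`, `locusB`,
#'   `environment`, `active` (and optionally `p`).
#' @return object of class `epistatic_network`: list with the igraph
#'   multigraph, the records, `nodes`, `environments`, the
#'   `interactor_counts` matrix (nodes x environments),
#'   `n_envs_epistatic` per node and `edge_env_counts` per pair.
#' @export
build_network <- function(records) {
  stopifnot(all(c("locusA", "locusB", "environment", "active") %in%
                  names(records)))
  if (!"p" %in% names(records)) records$p <- NA_real_
  envs <- sort(unique(as.character(records$environment)))
  act <- records[records$active, , drop = FALSE]
  nodes <- sort(unique(c(act$locusA, act$locusB)))
  graph <- igraph::graph_from_data_frame(
    act[, c("locusA", "locusB", "environment", "p"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  counts <- matrix(0L, nrow = length(nodes), ncol = length(envs),
                   dimnames = list(nodes, envs))
  for (e in envs) {
    sub <- act[act$environment == e, , drop = FALSE]
    for (v in unique(c(sub$locusA, sub$locusB))) {
      partners <- unique(c(sub$locusB[sub$locusA == v],
                           sub$locusA[sub$locusB == v]))
      counts[v, e] <- length(setdiff(partners, v))
    }
  }
  key <- .pair_key(act$locusA, act$locusB)
  edge_env <- if (nrow(act) > 0L) {
    agg <- stats::aggregate(list(n_envs_active = act$environment),
                            by = list(key = key),
                            FUN = function(x) length(unique(x)))
    first <- act[!duplicated(key), c("locusA", "locusB"), drop = FALSE]
    first$key <- key[!duplicated(key)]
    merge(first, agg, by = "key")[, c("locusA", "locusB", "n_envs_active")]
  } else {
    data.frame(locusA = character(), locusB = character(),
               n_envs_active = integer(), stringsAsFactors = FALSE)
  }
  structure(list(
    graph = graph, records = records, nodes = nodes, environments = envs,
    interactor_counts = counts,
    n_envs_epistatic = rowSums(counts > 0),
    edge_env_counts = edge_env
  ), class = "epistatic_network")
}

#' Hub loci of an epistatic network
#'
#' A hub is a locus with strictly more than `min_interactors` distinct
#' epistatic interactors in at least one single environment.
#'
#' @param net an `epistatic_network`.
#' @param min_interactors threshold (default 4; strict inequality).
#' @return character vector of hub marker ids.
#' @export
find_hubs <- function(net, min_interactors = 4) {
  stopifnot(inherits(net, "epistatic_network"))
  if (length(net$nodes) == 0L) return(character())
  mx <- apply(net$interactor_counts, 1L, max)
  names(mx)[mx > min_interactors]
}

# per-environment interactor counts of one node, names kept even for a
# single-environment network
.hub_counts <- function(net, hub) {
  stats::setNames(net$interactor_counts[hub, ],
                  colnames(net$interactor_counts))
}

# distinct active partners of `locus` in `environment`
.partners <- function(net, locus, environment) {
  act <- net$records[net$records$active &
                       net$records$environment == environment, , drop = FALSE]
  unique(c(act$locusB[act$locusA == locus], act$locusA[act$locusB == locus]))
}

#' Activity profile of a hub network across environments
#'
#' The hub's reference interactor set is fixed as its radial loci in the most
#' highly activated environment (the one with the largest interactor count;
#' ties broken by the alphabetically first label). For every environment the
#' report gives the fraction of reference interactors with an active epistatic
#' edge to the hub, and the fraction with a significant additive effect.
#'
#' @param net an `epistatic_network`.
#' @param additive additive effect table with a logical `significant` column
#'   (see [estimate_effects()] with `fdr`).
#' @param hub a hub marker id (see [find_hubs()]).
#' @return list of class `hub_report`: `hub`, `reference_env`,
#'   `interactors`, `active_fraction`, `additive_fraction` (named by
#'   environment).
#' @export
hub_activity_profile <- function(net, additive, hub) {
  stopifnot(inherits(net, "epistatic_network"))
  if (!hub %in% rownames(net$interactor_counts)) {
    stop("locus ", hub, " is not in the network")
  }
  counts <- .hub_counts(net, hub)
  ref_env <- names(counts)[order(-counts, names(counts))][1L]
  ref <- .partners(net, hub, ref_env)
  active_fraction <- vapply(net$environments, function(e)
    length(intersect(.partners(net, hub, e), ref)) / length(ref), numeric(1))
  if (!"significant" %in% names(additive)) {
    stop("additive table needs a 'significant' column; ",
         "use estimate_effects(..., fdr = )")
  }
  additive_fraction <- vapply(net$environments, function(e) {
    sig <- additive$locus[additive$environment == e & additive$significant]
    mean(ref %in% sig)
  }, numeric(1))
  structure(list(hub = hub, reference_env = ref_env, interactors = ref,
                 active_fraction = active_fraction,
                 additive_fraction = additive_fraction),
            class = "hub_report")
}

#' Fit and rank hub networks per environment
#'
#' For each hub network (hub plus its reference interactors, as in
#' [hub_activity_profile()]) and each environment, the segregant mean growth
#' is regressed jointly on the additive terms of all network loci plus the
#' hub-by-radial product interaction terms; the adjusted r-squared measures
#' the network's contribution to growth variance and networks are ranked
#' within each environment (1 = best fit). Aliased columns are dropped with a
#' warning.
#'
#' @param net an `epistatic_network`.
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param hubs hub marker ids (default [find_hubs()] on `net`).
#' @return data frame (`hub`, `environment`, `adj_r2`, `rank`,
#'   `n_interactors`).
#' @export
network_fit_rank <- function(net, geno, pheno, hubs = NULL) {
  hubs <- hubs %||% find_hubs(net)
  if (length(hubs) < 2L) stop("at least two hub networks are required")
  refsets <- lapply(hubs, function(h) {
    counts <- .hub_counts(net, h)
    ref_env <- names(counts)[order(-counts, names(counts))][1L]
    .partners(net, h, ref_env)
  })
  names(refsets) <- hubs
  rows <- do.call(rbind, lapply(net$environments, function(e) {
    al <- .segregant_means(geno, pheno, e)
    do.call(rbind, lapply(hubs, function(h) {
      ref <- refsets[[h]]
      gH <- al$G[, h]
      X <- cbind(`(Intercept)` = 1, gH, al$G[, ref, drop = FALSE],
                 al$G[, ref, drop = FALSE] * gH)
      colnames(X) <- c("(Intercept)", h, ref, paste0(h, ":", ref))
      fit <- .ols(X, al$y, allow_aliased = TRUE)
      data.frame(hub = h, environment = e, adj_r2 = fit$adj_r2,
                 n_interactors = length(ref), stringsAsFactors = FALSE)
    }))
  }))
  rows$rank <- stats::ave(-rows$adj_r2, rows$environment, FUN = function(x)
    rank(x, ties.method = "first"))
  rownames(rows) <- NULL
  rows
}

#' Network summary tables
#'
#' Summaries of the across-environment network: per-locus counts of
#' environments with at least one active epistatic interaction, per-locus
#' counts of environments with a significant additive effect, per-pair counts
#' of environments in which the interaction is active, and (when genotypes,
#' phenotypes and the full additive locus set are supplied) the
#' per-environment fraction of the additive genetic variance that the network
#' loci explain: adjusted r-squared of the network-loci additive model over
#' that of the full locus-set additive model, both clamped at 0 and the ratio
#' capped at 1.
#'
#' @param net an `epistatic_network`.
#' @param additive optional additive effect table with `significant` flags.
#' @param geno,pheno,full_loci optional; needed for the variance-explained
#'   table.
#' @return list of class `network_summary` with elements
#'   `locus_epistatic_envs`, `locus_additive_envs`, `edge_env_counts`,
#'   `variance_explained`.
#' @export
summarize_network <- function(net, additive = NULL, geno = NULL, pheno = NULL,
                              full_loci = NULL) {
  stopifnot(inherits(net, "epistatic_network"))
  locus_epi <- data.frame(locus = names(net$n_envs_epistatic),
                          n_envs = as.integer(net$n_envs_epistatic),
                          stringsAsFactors = FALSE)
  locus_add <- NULL
  if (!is.null(additive) && "significant" %in% names(additive)) {
    sub <- additive[additive$locus %in% net$nodes, , drop = FALSE]
    agg <- stats::aggregate(significant ~ locus, data = sub, FUN = sum)
    locus_add <- data.frame(locus = agg$locus,
                            n_envs = as.integer(agg$significant),
                            stringsAsFactors = FALSE)
  }
  var_explained <- NULL
  if (!is.null(geno) && !is.null(pheno) && !is.null(full_loci)) {
    full <- if (inherits(full_loci, "locus_set")) full_loci$loci else
      as.character(full_loci)
    net_loci <- intersect(net$nodes, colnames(geno))
    var_explained <- do.call(rbind, lapply(net$environments, function(e) {
      al <- .segregant_means(geno, pheno, e)
      a_net <- .ols(cbind(1, al$G[, net_loci, drop = FALSE]), al$y,
                    allow_aliased = TRUE)$adj_r2
      a_full <- .ols(cbind(1, al$G[, union(full, net_loci), drop = FALSE]),
                     al$y, allow_aliased = TRUE)$adj_r2
      a_net <- max(0, a_net)
      a_full <- max(0, a_full)
      data.frame(environment = e, adj_r2_network = a_net,
                 adj_r2_full = a_full,
                 fraction = if (a_full > 0) min(1, a_net / a_full) else
                   NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(locus_epistatic_envs = locus_epi,
                 locus_additive_envs = locus_add,
                 edge_env_counts = net$edge_env_counts,
                 variance_explained = var_explained),
            class = "network_summary")
}
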
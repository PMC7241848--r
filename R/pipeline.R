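#' Default pipeline configuration
#'
#' @param ... overrides of the defaults.
#' @return a named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  utils::modifyList(list(
    seed = 1L,
    simulate = TRUE,
    n_segregants = 800L,
    n_envs = 6L,
    hub_spec = list(),
    genotypes = NULL, phenotypes = NULL, map = NULL, seed_pairs = NULL,
    prune_dist_bp = 20000, prune_r2 = 0.9,
    fdr = 0.05,
    scan_alpha = 0.05,
    lenient_alpha = 0.05, lenient_per_env = FALSE,
    hub_min_interactors = 4,
    gxe_alpha = 0.05,
    n_perm = 0L
  ), list(...))
}

.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + stage * 7919L) %% 2147483647L
}

#' Run the full G-by-G-by-E analysis pipeline
#'
#' Orchestrates the stages end to end: (1) simulate a synthetic panel (or
#' load genotype/phenotype files), (2) partition growth variance into G and
#' G-by-E, (3) define the additive locus set (marginal scan, linkage pruning,
#' polygenic FDR selection) and estimate joint additive effects per
#' environment, (4) test every selected locus for G-by-E interaction, (5)
#' re-test the candidate interaction pairs in every environment and build the
#' across-environment epistatic network with hub detection, (6) quantify
#' capacitation for each hub in its most activated environment, and (7)
#' compute the population-level dynamics statistics. All stage outputs plus a
#' reproducibility manifest are written under `out_dir`.
#'
#' @param config a list from [pipeline_config()] or a path to a YAML file
#'   with the same fields.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- do.call(pipeline_config, config)
  stages <- character()
  # fail before any computation if declared inputs are unreadable
  if (!isTRUE(config$simulate)) {
    for (f in c("genotypes", "phenotypes", "map")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("config error: simulate is FALSE and ", f,
             " path is missing or unreadable")
      }
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[length(stages) + 1L]] <<- name
    res
  }

  sim <- run_stage("simulate", {
    if (isTRUE(config$simulate)) {
      arch <- make_paperlike_arch(config$n_envs, config$hub_spec,
                                  seed = .stage_seed(config$seed, 1L))
      geno <- simulate_genotypes(config$n_segregants, arch$map,
                                 seed = .stage_seed(config$seed, 2L))
      pheno <- simulate_phenotypes(geno, arch,
                                   seed = .stage_seed(config$seed, 3L))
      write_genotypes(geno, file.path(out_dir, "genotypes.tsv"))
      write_map(arch$map, file.path(out_dir, "map.tsv"))
      write_phenotypes(pheno, file.path(out_dir, "phenotypes.tsv"))
      arch_to_json(arch, file.path(out_dir, "architecture.json"))
      list(geno = geno, pheno = pheno, map = arch$map, arch = arch,
           seed_pairs = truth_pairs(arch))
    } else {
      list(geno = read_genotypes(config$genotypes),
           pheno = read_phenotypes(config$phenotypes),
           map = read_map(config$map),
           arch = NULL,
           seed_pairs = if (!is.null(config$seed_pairs))
             utils::read.delim(config$seed_pairs,
                               stringsAsFactors = FALSE) else NULL)
    }
  })
  geno <- sim$geno
  pheno <- sim$pheno
  envs <- .environments(pheno)

  varcomp <- run_stage("partition", partition_gxe(pheno))
  jsonlite::write_json(unclass(varcomp)[c("SS_G", "SS_E", "SS_GxE",
                                          "SS_resid", "SS_total",
                                          "fraction_G", "fraction_E",
                                          "fraction_GxE", "grand_mean")],
                       file.path(out_dir, "varcomp.json"),
                       auto_unbox = TRUE, digits = NA)

  addres <- run_stage("additive", {
    peaks <- do.call(rbind, lapply(envs, function(e) {
      sc <- marginal_scan(geno, pheno, e)
      sc[sc$p < config$scan_alpha / nrow(sc) & !sc$monomorphic, ,
         drop = FALSE]
    }))
    if (nrow(peaks) == 0L) stop("no marginal peaks detected")
    pruned <- prune_loci(peaks, geno, sim$map,
                         max_dist_bp = config$prune_dist_bp,
                         min_r2 = config$prune_r2)
    selected <- polygenic_select(geno, pheno, pruned, fdr = config$fdr)
    effects <- estimate_effects(geno, pheno, selected, fdr = config$fdr)
    utils::write.table(effects, file.path(out_dir, "additive_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(peaks = peaks, loci = selected, effects = effects)
  })

  gxe <- run_stage("gxe", {
    res <- test_gxe_all(geno, pheno, addres$loci, alpha = config$gxe_alpha)
    utils::write.table(res, file.path(out_dir, "gxe_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  netres <- run_stage("network", {
    seed_pairs <- sim$seed_pairs
    if (is.null(seed_pairs) || nrow(seed_pairs) == 0L) {
      stop("no candidate interaction pairs available")
    }
    records <- retest_across_envs(geno, pheno, seed_pairs,
                                  alpha = config$lenient_alpha,
                                  correct_per_env = config$lenient_per_env)
    net <- build_network(records)
    write_interactions(records, file.path(out_dir, "interactions.tsv"))
    if (length(net$nodes) > 0L) {
      write_network(net, file.path(out_dir, "network_edges.tsv"),
                    file.path(out_dir, "network.graphml"))
    }
    hubs <- find_hubs(net, config$hub_min_interactors)
    jsonlite::write_json(list(hubs = hubs,
                              n_pairs = attr(records, "n_pairs"),
                              threshold = attr(records, "threshold")),
                         file.path(out_dir, "hubs.json"),
                         auto_unbox = TRUE, digits = NA)
    list(records = records, net = net, hubs = hubs)
  })

  cap <- run_stage("capacitation", {
    lapply(netres$hubs, function(h) {
      counts <- .hub_counts(netres$net, h)
      ref_env <- names(counts)[order(-counts, names(counts))][1L]
      radials <- .partners(netres$net, h, ref_env)
      tryCatch(conditional_h2(geno, pheno, h, radials, ref_env),
               error = function(e) list(hub = h, error = conditionMessage(e)))
    })
  })
  jsonlite::write_json(
    lapply(cap, function(cs) if (!is.null(cs$error)) cs else
      list(hub = cs$hub, environment = cs$environment,
           h2_allele0 = cs$h2_allele0, h2_allele2 = cs$h2_allele2,
           delta_h2 = cs$delta_h2)),
    file.path(out_dir, "capacitation.json"), auto_unbox = TRUE, digits = NA)

  dyn <- run_stage("dynamics", {
    summaries <- env_variance_summary(geno, pheno, addres$loci, netres$net)
    dynl <- effect_variance_by_locus(addres$effects, netres$net)
    vvc <- tryCatch(variance_vs_connectivity(dynl),
                    error = function(e) list(error = conditionMessage(e)))
    hvn <- tryCatch(hub_vs_nonhub_test(dynl),
                    error = function(e) list(error = conditionMessage(e)))
    tve <- tryCatch(total_variance_vs_edges(summaries,
                                            n_perm = config$n_perm),
                    error = function(e) list(error = conditionMessage(e)))
    utils::write.table(summaries, file.path(out_dir, "env_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(variance_vs_connectivity = vvc,
                              hub_vs_nonhub = hvn,
                              total_variance_vs_edges = tve),
                         file.path(out_dir, "dynamics.json"),
                         auto_unbox = TRUE, digits = NA)
    list(summaries = summaries, locus_dynamics = dynl,
         variance_vs_connectivity = vvc, hub_vs_nonhub = hvn,
         total_variance_vs_edges = tve)
  })

  manifest <- list(
    package = "ggxe",
    version = as.character(utils::packageVersion("ggxe")),
    r_version = R.version.string,
    seed = config$seed,
    stages = stages,
    config = config[setdiff(names(config), "hub_spec")],
    hub_spec = config$hub_spec
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(sim = sim, varcomp = varcomp, additive = addres, gxe = gxe,
                 network = netres, capacitation = cap, dynamics = dyn,
                 manifest = manifest))
}
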
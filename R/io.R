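#' @name ggxe-io
#' @title Readers and writers for panel artefacts
#'
#' @description All tables are tab-separated UTF-8 with a header row.
#' Genotypes: first column `segregant`, remaining columns marker ids, cells
#' 0/2. Map: `marker`, `chrom`, `pos_bp`, `pos_cM`. Phenotypes (long format):
#' `segregant`, `environment`, `replicate`, `growth`. Interactions:
#' `locusA`, `locusB`, `environment`, `LR`, `p`, `active`. Architectures are
#' serialised to JSON. Every write/read pair round-trips losslessly and
#' validation errors name the offending row and column.
NULL

#' @rdname ggxe-io
#' @param geno genotype matrix (segregants x markers, values 0/2).
#' @param path file path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(segregant = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ggxe-io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "segregant") {
    stop("genotype file must have 'segregant' as its first column: ", path)
  }
  geno <- as.matrix(df[, -1L, drop = FALSE])
  rownames(geno) <- df$segregant
  bad <- which(!(geno %in% c(0, 2)) | is.na(geno))
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(geno)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(geno)) + 1L
    stop("invalid genotype value '", geno[i, j], "' at row ", i,
         " (segregant '", rownames(geno)[i], "'), column '",
         colnames(geno)[j], "': haploid genotypes must be coded 0/2")
  }
  storage.mode(geno) <- "integer"
  geno
}

#' @rdname ggxe-io
#' @param map genetic map data frame.
#' @export
write_map <- function(map, path) {
  validate_genetic_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ggxe-io
#' @export
read_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_genetic_map(map)
  map
}

#' @rdname ggxe-io
#' @param pheno long-format phenotype data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno[, c("segregant", "environment", "replicate",
                               "growth")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ggxe-io
#' @param environments optional declared environment set; labels outside it
#'   are a validation error.
#' @export
read_phenotypes <- function(path, environments = NULL) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("segregant", "environment", "replicate", "growth")
  missing <- setdiff(required, names(ph))
  if (length(missing) > 0L) {
    stop("phenotype file is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(environments)) {
    bad <- which(!ph$environment %in% environments)
    if (length(bad) > 0L) {
      stop("unknown environment label '", ph$environment[bad[1L]],
           "' at row ", bad[1L], " of ", path)
    }
  }
  if (any(!is.finite(ph$growth))) {
    stop("non-finite growth value at row ",
         which(!is.finite(ph$growth))[1L], " of ", path)
  }
  ph
}

#' @rdname ggxe-io
#' @param records interaction record data frame.
#' @export
write_interactions <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname ggxe-io
#' @export
read_interactions <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("locusA", "locusB", "environment", "LR", "p", "active")
  missing <- setdiff(required, names(rec))
  if (length(missing) > 0L) {
    stop("interaction file is missing columns: ",
         paste(missing, collapse = ", "))
  }
  same <- which(rec$locusA == rec$locusB)
  if (length(same) > 0L) {
    stop("interaction row ", same[1L], " pairs locus '", rec$locusA[same[1L]],
         "' with itself")
  }
  badp <- which(!is.na(rec$p) & (rec$p < 0 | rec$p > 1))
  if (length(badp) > 0L) {
    stop("p-value outside [0,1] at interaction row ", badp[1L])
  }
  badlr <- which(!is.na(rec$LR) & rec$LR < 0)
  if (length(badlr) > 0L) {
    stop("negative LR statistic at interaction row ", badlr[1L])
  }
  key <- paste(.pair_key(rec$locusA, rec$locusB), rec$environment)
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (pair, environment) interaction at row ", dup[1L], ": ",
         rec$locusA[dup[1L]], "-", rec$locusB[dup[1L]], " in ",
         rec$environment[dup[1L]])
  }
  rec$active <- as.logical(rec$active)
  rec
}

#' Serialise a simulation architecture to JSON
#'
#' @param arch a `sim_architecture`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
arch_to_json <- function(arch, path = NULL) {
  validate_architecture(arch)
  payload <- list(
    environments = arch$environments,
    additive = arch$additive,
    epistatic = arch$epistatic,
    capacitors = lapply(arch$capacitors, function(cp) {
      list(hub = cp$hub, masking_allele = cp$masking_allele,
           radials = cp$radials)
    }),
    residual_sd = as.list(arch$residual_sd),
    replicates = arch$replicates,
    env_main = as.list(arch$env_main),
    map = arch$map
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "columns")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a simulation architecture from JSON
#'
#' @param path file path or a JSON string produced by [arch_to_json()].
#' @return a `sim_architecture`.
#' @export
arch_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  as_df <- function(x, cols) {
    if (is.null(x) || length(x) == 0L || sum(lengths(x)) == 0L) return(NULL)
    out <- as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
    out[, cols, drop = FALSE]
  }
  unlist_named <- function(x) {
    v <- unlist(x)
    if (length(v) == 1L && (is.null(names(v)) || names(v) == "")) {
      v <- unname(v)
    }
    v
  }
  caps <- lapply(payload$capacitors, function(cp) {
    list(hub = cp$hub, masking_allele = cp$masking_allele,
         radials = as_df(cp$radials, c("locus", "environment", "effect")))
  })
  sim_architecture(
    environments = payload$environments,
    additive = as_df(payload$additive, c("locus", "environment", "effect")),
    epistatic = as_df(payload$epistatic,
                      c("locusA", "locusB", "environment", "effect")),
    capacitors = caps,
    residual_sd = unlist_named(payload$residual_sd),
    replicates = payload$replicates,
    env_main = unlist_named(payload$env_main),
    map = if (is.null(payload$map)) NULL else
      as.data.frame(payload$map, stringsAsFactors = FALSE)
  )
}

#' Export an epistatic network
#'
#' Writes the active edges as a tab-separated edge list
#' (`locusA`, `locusB`, `environment`, `p`) and, optionally, the multigraph
#' in GraphML for use in external network tools.
#'
#' @param net an `epistatic_network` (see [build_network()]).
#' @param edge_path path for the edge-list TSV.
#' @param graphml_path optional path for a GraphML export.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  stopifnot(inherits(net, "epistatic_network"))
  act <- net$records[net$records$active, c("locusA", "locusB", "environment",
                                           "p"), drop = FALSE]
  utils::write.table(act, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
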
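# Pipeline driver: runs the stages end to end (or singly) from one config,
# writing standard artifacts with deterministic per-stage seeding and a
# manifest.

#' Default pipeline configuration
#'
#' Defaults follow the method's standard parameters: k = 10 neighbors,
#' minimum module size 5, MCODE node score cutoff 0.2 with haircut, 1000
#' cross-talk permutations at alpha 0.05, 400 Cox resamples of 90% of the
#' training samples at alpha 0.05, GeneRank damping d = 0.70, top 5%
#' selection.
#'
#' @return Named list of defaults; override any field via `run_pipeline()`'s
#'   config.
#' @export
default_config <- function() {
  list(k_neighbors = 10, ranking = "absolute",
       min_module_size = 5, node_score_cutoff = 0.2, haircut = TRUE,
       n_permutations = 1000, alpha = 0.05,
       n_rep = 400, sample_fraction = 0.9, cox_alpha = 0.05,
       d = 0.70, fraction = 0.05,
       seed = 1)
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_config(), config)
  num_fields <- c("k_neighbors", "min_module_size", "node_score_cutoff",
                  "n_permutations", "alpha", "n_rep", "sample_fraction",
                  "cox_alpha", "d", "fraction", "seed")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1)
      stop("config field '", f, "' must be a single number")
  }
  cfg
}

artifact_paths <- function(outdir) {
  list(network = file.path(outdir, "network.graphml"),
       qc = file.path(outdir, "network_qc.json"),
       modules = file.path(outdir, "modules.tsv"),
       module_network = file.path(outdir, "module_network.graphml"),
       profiles = file.path(outdir, "profiles.tsv"),
       generank = file.path(outdir, "generank.tsv"),
       survival = file.path(outdir, "survival_eval.tsv"),
       dscore = file.path(outdir, "dscore.json"),
       enrichment = file.path(outdir, "enrichment.tsv"),
       manifest = file.path(outdir, "manifest.json"))
}

pipeline_inputs <- function(cfg) {
  expr <- read_expression(cfg$expression, probe_map = if (!is.null(cfg$probe_map))
    read_probe_map(cfg$probe_map) else NULL)
  clinical <- read_clinical(cfg$clinical)
  al <- align_samples(expr, clinical)
  al
}

#' Run the full prognostic-module pipeline
#'
#' Stages: co-expression network (`network`), module detection (`modules`),
#' cross-talk network (`modnet`), prognostic profiling (`profile`), GeneRank
#' prioritization and selection (`rank`), survival evaluation (`evaluate`),
#' and enrichment (`enrich`, if annotation lists are configured). Artifacts
#' are written to `outdir` and listed, with checksums, in `manifest.json`.
#' Per-stage seeds are derived from the master `seed` at fixed offsets so a
#' stage rerun alone reproduces its full-pipeline result.
#'
#' @param config Named list or path to a YAML file. Required fields:
#'   `expression`, `clinical`, `outdir`. Optional: `probe_map`,
#'   `test_expression`/`test_clinical` (held-out evaluation cohort),
#'   `annotations` (named list of gene-list files), and any
#'   [default_config()] parameter.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$expression) || is.null(cfg$clinical) || is.null(cfg$outdir))
    stop("config must name 'expression', 'clinical' and 'outdir'")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- artifact_paths(cfg$outdir)
  seeds <- derive_seeds(cfg$seed, 4)
  inp <- pipeline_inputs(cfg)

  if (cfg$k_neighbors >= nrow(inp$expr))
    stop("config field 'k_neighbors' must be smaller than the gene count")
  message("stage network: ", nrow(inp$expr), " genes, ",
          ncol(inp$expr), " samples")
  corr <- pearson_cor(inp$expr)
  net <- build_rank_network(corr, k = cfg$k_neighbors, ranking = cfg$ranking)
  export_graph(net, paths$network, "graphml")
  qc <- network_qc(net)
  jsonlite::write_json(qc, paths$qc, auto_unbox = TRUE, digits = NA)
  message("stage network: ", igraph::vcount(net), " nodes, ",
          igraph::ecount(net), " union edges (",
          qc$selection_count, " selections), mean neighbors ",
          round(qc$mean_neighbors, 2))

  mods <- detect_modules(net, node_score_cutoff = cfg$node_score_cutoff,
                         haircut = cfg$haircut,
                         min_size = cfg$min_module_size)
  write_modules(mods, paths$modules)
  message("stage modules: ", nrow(mods), " modules of size >= ",
          cfg$min_module_size)
  if (nrow(mods) < 2) stop("stage modules: fewer than 2 modules detected")

  modnet <- build_module_network(net, mods, n_perm = cfg$n_permutations,
                                 alpha = cfg$alpha, seed = seeds[1])
  export_graph(modnet, paths$module_network, "graphml")
  message("stage modnet: ", igraph::ecount(modnet),
          " cross-talk edges among ", nrow(mods), " modules")

  prof <- profile_all(inp$expr, mods, inp$clinical, n_rep = cfg$n_rep,
                      sample_fraction = cfg$sample_fraction,
                      cox_alpha = cfg$cox_alpha, seed = seeds[2])
  write.table(prof, paths$profiles, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("stage profile: ", nrow(prof), " modules profiled (",
          cfg$n_rep, " resamples)")

  ranked <- generank_modules(modnet, prof, d = cfg$d)
  sel <- select_top(ranked, fraction = cfg$fraction, count = cfg$select_count)
  ranked$selected <- ranked$module_id %in% sel
  write.table(ranked, paths$generank, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("stage rank: ", length(sel), " modules selected")

  sel_mods <- mods[mods$module_id %in% sel, , drop = FALSE]
  datasets <- list(training = list(expr = inp$expr, clinical = inp$clinical))
  if (!is.null(cfg$test_expression)) {
    te <- align_samples(read_expression(cfg$test_expression),
                        read_clinical(cfg$test_clinical))
    datasets$test <- list(expr = te$expr, clinical = te$clinical)
  }
  ev <- evaluate_modules(datasets, sel_mods, prof)
  write.table(ev$per_dataset, paths$survival, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(dscore = ev$dscore), paths$dscore,
                       auto_unbox = TRUE, digits = NA)
  message("stage evaluate: Dscore ", round(ev$dscore, 3))

  enr <- NULL
  if (!is.null(cfg$annotations)) {
    ann <- lapply(cfg$annotations, read_gene_list)
    universe <- igraph::V(net)$name
    query <- unique(unlist(sel_mods$genes))
    enr <- test_enrichment(query, ann, universe)
    write.table(enr, paths$enrichment, sep = "\t", quote = FALSE,
                row.names = FALSE)
    message("stage enrich: ", nrow(enr), " annotation lists tested")
  }

  manifest <- write_manifest(paths, cfg)
  invisible(list(network = net, qc = qc, modules = mods,
                 module_network = modnet, profiles = prof, ranked = ranked,
                 selected = sel, evaluation = ev, enrichment = enr,
                 manifest = manifest))
}

write_manifest <- function(paths, cfg) {
  files <- Filter(file.exists, unlist(paths[names(paths) != "manifest"]))
  manifest <- list(
    package = "prognet",
    version = as.character(utils::packageVersion("prognet")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("expression", "clinical"))],
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  manifest
}

#' Run one pipeline stage against saved artifacts
#'
#' Re-executes a single stage, reading its inputs from the artifacts a
#' previous [run_pipeline()] left in `outdir`. Stages: `"network"`,
#' `"modules"`, `"modnet"`, `"profile"`, `"rank"`.
#'
#' @param stage Stage name.
#' @param config As for [run_pipeline()].
#' @return The stage's result object, invisibly; the stage artifact is
#'   rewritten.
#' @export
run_stage <- function(stage, config) {
  cfg <- load_config(config)
  paths <- artifact_paths(cfg$outdir)
  seeds <- derive_seeds(cfg$seed, 4)
  need <- function(p) {
    if (!file.exists(p)) stop("missing upstream artifact: ", p)
    p
  }
  switch(stage,
    network = {
      inp <- pipeline_inputs(cfg)
      net <- build_rank_network(pearson_cor(inp$expr), k = cfg$k_neighbors,
                                ranking = cfg$ranking)
      export_graph(net, paths$network, "graphml")
      invisible(net)
    },
    modules = {
      net <- igraph::read_graph(need(paths$network), format = "graphml")
      mods <- detect_modules(net, node_score_cutoff = cfg$node_score_cutoff,
                             haircut = cfg$haircut,
                             min_size = cfg$min_module_size)
      write_modules(mods, paths$modules)
      invisible(mods)
    },
    modnet = {
      net <- igraph::read_graph(need(paths$network), format = "graphml")
      mods <- read_modules(need(paths$modules))
      modnet <- build_module_network(net, mods, n_perm = cfg$n_permutations,
                                     alpha = cfg$alpha, seed = seeds[1])
      export_graph(modnet, paths$module_network, "graphml")
      invisible(modnet)
    },
    profile = {
      inp <- pipeline_inputs(cfg)
      mods <- read_modules(need(paths$modules))
      prof <- profile_all(inp$expr, mods, inp$clinical, n_rep = cfg$n_rep,
                          sample_fraction = cfg$sample_fraction,
                          cox_alpha = cfg$cox_alpha, seed = seeds[2])
      write.table(prof, paths$profiles, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      invisible(prof)
    },
    rank = {
      modnet <- igraph::read_graph(need(paths$module_network),
                                   format = "graphml")
      prof <- read.table(need(paths$profiles), header = TRUE, sep = "\t")
      ranked <- generank_modules(modnet, prof, d = cfg$d)
      sel <- select_top(ranked, fraction = cfg$fraction,
                        count = cfg$select_count)
      ranked$selected <- ranked$module_id %in% sel
      write.table(ranked, paths$generank, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      invisible(ranked)
    },
    stop("unknown stage '", stage,
         "'; expected network, modules, modnet, profile or rank")
  )
}
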
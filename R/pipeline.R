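#' Full-pipeline configuration
#'
#' Bundles every stage's parameters: input paths, ego-extraction settings,
#' the equivalence predicate set, Louvain settings, centrality parameters,
#' TNCS normalization, and one global seed from which all stage seeds derive.
#'
#' @param graph_path Path to the knowledge graph file (see [read_kg()]).
#' @param seeds_path Path to the seed disease cluster (one ID per line).
#' @param out_dir Output directory (created if missing).
#' @param radius,mode Ego-extraction settings, see [build_profile_network()].
#' @param predicates Equivalence predicates triggering contraction.
#' @param resolution,min_community_size Louvain resolution and the minimum
#'   community size retained for ranking.
#' @param centrality A [centrality_config()].
#' @param scope,k TNCS normalization scope and top-list size.
#' @param seed Global integer seed.
#' @param format Graph file format passed to [read_kg()]/[write_kg()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(graph_path, seeds_path, out_dir,
                            radius = 3, mode = "all",
                            predicates = kg_equivalence_predicates(),
                            resolution = 1, min_community_size = 4,
                            centrality = centrality_config(),
                            scope = "top5_union", k = 5, seed = 1L,
                            format = "auto") {
  structure(list(graph_path = graph_path, seeds_path = seeds_path,
                 out_dir = out_dir, radius = radius, mode = mode,
                 predicates = predicates, resolution = resolution,
                 min_community_size = min_community_size,
                 centrality = centrality, scope = scope, k = k,
                 seed = as.integer(seed), format = format),
            class = "pipeline_config")
}

#' Run the disease-profile network pipeline end to end
#'
#' Stages: read graph and seed cluster, build the profile network by
#' radius-limited ego-graph union, contract equivalence components, partition
#' into modularity classes with Louvain, rank classes by modularity score,
#' compute the five within-class centralities, and rank candidates by TNCS.
#' All artifacts are written to `out_dir` together with a JSON manifest
#' recording the configuration, seed, and per-stage node/edge counts. A
#' failing stage aborts with the stage name; artifacts of completed stages
#' are retained. Identical configurations (including the seed) yield
#' byte-identical candidate reports.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results: `profile_network`,
#'   `contracted`, `partition`, `report`, `manifest`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("Pipeline stage \"", name, "\" failed: ",
                   conditionMessage(e))))
  }

  graph <- stage("read", read_kg(config$graph_path, config$format))
  seeds <- stage("read", read_seed_cluster(config$seeds_path))

  pn <- stage("extract", build_profile_network(graph, seeds,
                                               radius = config$radius,
                                               mode = config$mode))
  write_kg(pn, out("profile_network.graphml"), "graphml")

  contracted <- stage("contract", contract_kg(pn, predicates = config$predicates))
  write_kg(contracted, out("contracted_network.graphml"), "graphml")
  write_merge_report(contracted, out("merge_report.json"))

  partition <- stage("cluster", louvain_partition(contracted,
                                                  resolution = config$resolution,
                                                  seed = config$seed))
  readr::write_csv(tidy(partition), out("partition.csv"))
  scores <- stage("cluster", community_scores(contracted, partition))
  readr::write_csv(scores, out("community_scores.csv"))

  report <- stage("rank", rank_candidates(contracted, partition,
                                          min_size = config$min_community_size,
                                          resolution = config$resolution,
                                          config = config$centrality,
                                          scope = config$scope, k = config$k))
  readr::write_csv(report$records, out("centrality_tncs.csv"))
  write_candidate_report(report, out("candidates.json"), out("candidates.md"))

  manifest <- list(
    seed = config$seed,
    radius = config$radius, mode = config$mode,
    predicates = config$predicates,
    resolution = config$resolution,
    min_community_size = config$min_community_size,
    scope = config$scope, k = config$k,
    stages = list(
      input = list(n_nodes = igraph::vcount(graph),
                   n_edges = igraph::ecount(graph),
                   n_seeds = length(seeds)),
      extracted = list(n_nodes = igraph::vcount(pn),
                       n_edges = igraph::ecount(pn)),
      optimized = list(n_nodes = igraph::vcount(contracted),
                       n_edges = igraph::ecount(contracted),
                       n_merged_nodes = nrow(merge_report(contracted))),
      clustered = list(n_communities = partition$n_communities,
                       n_ranked = nrow(report$communities)),
      ranked = list(n_candidates = nrow(report$candidates))
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(profile_network = pn, contracted = contracted,
                 partition = partition, report = report, manifest = manifest))
}

#' Simulate a knowledge graph to files
#'
#' Generates a synthetic knowledge graph, its seed disease cluster and the
#' ground truth, and writes them to a directory: `graph.graphml`,
#' `seeds.txt`, `truth.json`.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the three file paths.
#' @export
simulate_kg <- function(config = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_kg(config)
  seeds <- generate_seed_cluster(config, sim$truth)
  paths <- list(graph = file.path(dir, "graph.graphml"),
                seeds = file.path(dir, "seeds.txt"),
                truth = file.path(dir, "truth.json"))
  write_kg(sim$graph, paths$graph, "graphml")
  write_seed_cluster(seeds, paths$seeds)
  jsonlite::write_json(
    list(equivalence_components = sim$truth$equivalence_components,
         community_of = as.list(sim$truth$community_of),
         hubs = as.list(sim$truth$hubs),
         seed_cluster = seeds),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
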
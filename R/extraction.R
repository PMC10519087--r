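#' Ego subgraph of a knowledge graph
#'
#' Returns the subgraph induced on all nodes within `radius` hops of a center
#' node. By default traversal ignores edge direction, since equivalence edges
#' are semantically symmetric; `mode = "out"` / `"in"` follow only outgoing /
#' incoming edges for sensitivity analyses. All edges of the input graph
#' between retained nodes are kept.
#'
#' @param graph A knowledge graph.
#' @param center Node ID of the ego center.
#' @param radius Hop count (default 3).
#' @param mode Traversal direction: `"all"` (default), `"out"`, or `"in"`.
#' @return The induced ego subgraph as a knowledge graph.
#' @export
ego_subgraph <- function(graph, center, radius = 3,
                         mode = c("all", "out", "in")) {
  mode <- match.arg(mode)
  if (!center %in% igraph::V(graph)$name)
    abort(paste0("Center node not in graph: ", center))
  if (radius < 0) abort("`radius` must be >= 0.")
  nb <- igraph::ego(graph, order = radius, nodes = center, mode = mode)[[1]]
  as_kg(igraph::induced_subgraph(graph, nb))
}

#' Build a disease-profile network by ego-graph union
#'
#' The profile network for a cluster of related diseases is the union of the
#' radius-`radius` ego graphs centered on each seed disease: its node set is
#' the union of the per-seed ego node sets and its edge set is the input
#' graph's induced edges on that union (so the profile network is always an
#' induced subgraph of the knowledge graph). Seeds absent from the graph are
#' skipped with a warning reporting their count.
#'
#' @inheritParams ego_subgraph
#' @param seeds Character vector of seed disease node IDs (see
#'   [read_seed_cluster()]).
#' @return The profile network as a knowledge graph.
#' @examples
#' sim <- generate_kg(synth_config(n_diseases = 20, n_genes = 10,
#'                                 n_drugs = 5, n_phenotypes = 5,
#'                                 n_communities = 2, seed = 7))
#' seeds <- generate_seed_cluster(synth_config(n_diseases = 20, n_genes = 10,
#'                                             n_drugs = 5, n_phenotypes = 5,
#'                                             n_communities = 2,
#'                                             n_seed_diseases = 3, seed = 7),
#'                                sim$truth)
#' pn <- build_profile_network(sim$graph, seeds, radius = 3)
#' @export
build_profile_network <- function(graph, seeds, radius = 3,
                                  mode = c("all", "out", "in")) {
  mode <- match.arg(mode)
  seeds <- unique(as.character(seeds))
  present <- seeds %in% igraph::V(graph)$name
  if (any(!present))
    warn(paste0(sum(!present), " of ", length(seeds),
                " seed(s) not found in graph and skipped: ",
                paste(seeds[!present], collapse = ", ")))
  seeds <- seeds[present]
  if (length(seeds) == 0) abort("No seed node resolves in the graph.")
  nbs <- igraph::ego(graph, order = radius, nodes = seeds, mode = mode)
  keep <- unique(unlist(lapply(nbs, as.integer)))
  as_kg(igraph::induced_subgraph(graph, keep))
}
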
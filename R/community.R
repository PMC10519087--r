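#' Louvain partition of a profile network
#'
#' Partitions the undirected view of the graph into modularity classes with
#' the Louvain algorithm at resolution `resolution` (1.0 by default; smaller
#' values yield more, smaller communities). The local-move phase visits nodes
#' in a seeded random order when `randomize = TRUE`, making the run
#' reproducible for a given seed — re-run with several seeds and
#' [partition_stability()] to gauge how stable the classes are.
#'
#' @param graph A knowledge graph.
#' @param resolution Positive resolution parameter gamma (default 1).
#' @param seed Integer seed for the randomized node order.
#' @param randomize Randomize the local-move order (default `TRUE`); when
#'   `FALSE` nodes are visited in graph order.
#' @return A `kg_partition`: list with `membership` (named integer vector,
#'   community indices contiguous from 0), `n_communities`, `resolution`,
#'   `seed`, `modularity`.
#' @export
louvain_partition <- function(graph, resolution = 1, seed = 1L,
                              randomize = TRUE) {
  if (resolution <= 0) abort("`resolution` must be > 0.")
  if (igraph::vcount(graph) == 0) abort("Cannot partition an empty graph.")
  u <- .kg_und_simple(graph)
  withr::local_seed(as.integer(seed))
  perm <- if (randomize) sample(igraph::vcount(u)) else seq_len(igraph::vcount(u))
  up <- igraph::permute(u, order(perm))
  cl <- igraph::cluster_louvain(up, resolution = resolution)
  memb <- igraph::membership(cl)
  memb <- stats::setNames(as.integer(memb), igraph::V(up)$name)
  memb <- memb[igraph::V(u)$name]
  # renumber contiguously from 0 in order of first appearance
  memb <- stats::setNames(as.integer(match(memb, unique(memb))) - 1L,
                          names(memb))
  structure(list(membership = memb,
                 n_communities = length(unique(memb)),
                 resolution = resolution, seed = as.integer(seed),
                 modularity = if (igraph::ecount(u) > 0)
                   igraph::modularity(u, memb + 1L, resolution = resolution)
                 else NA_real_),
            class = "kg_partition")
}

#' @method print kg_partition
#' @export
print.kg_partition <- function(x, ...) {
  cat("<kg_partition> ", length(x$membership), " nodes in ",
      x$n_communities, " communities (resolution ", x$resolution,
      ", modularity ", signif(x$modularity, 4), ")\n", sep = "")
  invisible(x)
}

#' Tidiers for profnet result objects
#'
#' [generics::tidy()] returns one row per element (node-to-community
#' assignments for a partition, node-level TNCS records for a candidate
#' report, component membership for a merge plan); [generics::glance()]
#' returns a one-row summary.
#'
#' @param x A `kg_partition`, `merge_plan`, or `candidate_report`.
#' @param ... Unused.
#' @name profnet-tidiers
#' @return A tibble.
NULL

#' @rdname profnet-tidiers
#' @export
tidy.kg_partition <- function(x, ...) {
  tibble(node_id = names(x$membership), community = unname(x$membership))
}

#' @rdname profnet-tidiers
#' @export
glance.kg_partition <- function(x, ...) {
  tibble(n_nodes = length(x$membership), n_communities = x$n_communities,
         modularity = x$modularity, resolution = x$resolution, seed = x$seed)
}

#' Per-community modularity score
#'
#' The score of community c is `L_c/m - gamma * (k_c/(2m))^2`, where `L_c` is
#' the number of intra-community edges, `k_c` the sum of member degrees, `m`
#' the total edge count of the (undirected, simple) partitioned graph and
#' `gamma` the resolution. A high-scoring community has many internal and few
#' external connections — the hub-rich classes worth mining for repurposing
#' candidates. Summed over all communities at `gamma = 1` the scores equal
#' the partition's Newman modularity Q.
#'
#' @param graph The partitioned knowledge graph.
#' @param partition A `kg_partition` from [louvain_partition()].
#' @param community Community index (0-based, as in the partition).
#' @param resolution Resolution gamma used in the penalty term (default the
#'   partition's own resolution).
#' @return One-row tibble: `community`, `n_nodes`, `L_c`, `k_c`, `m`,
#'   `resolution`, `score`.
#' @export
community_score <- function(graph, partition, community,
                            resolution = partition$resolution) {
  u <- .kg_und_simple(graph)
  m <- igraph::ecount(u)
  if (m == 0) abort("Cannot score communities of a graph with no edges.")
  memb <- partition$membership[igraph::V(u)$name]
  if (!community %in% memb)
    abort(paste0("No community with index ", community, "."))
  members <- which(memb == community)
  sub <- igraph::induced_subgraph(u, members)
  L_c <- igraph::ecount(sub)
  k_c <- sum(igraph::degree(u, v = members))
  tibble(community = as.integer(community), n_nodes = length(members),
         L_c = L_c, k_c = k_c, m = m, resolution = resolution,
         score = L_c / m - resolution * (k_c / (2 * m))^2)
}

#' Score all communities of a partition
#'
#' @inheritParams community_score
#' @return A tibble with one [community_score()] row per community.
#' @export
community_scores <- function(graph, partition,
                             resolution = partition$resolution) {
  map_dfr(sort(unique(partition$membership)), function(k)
    community_score(graph, partition, k, resolution))
}

#' Rank communities by modularity score
#'
#' Drops communities that are too small to support meaningful within-class
#' network analysis (fewer than `min_size` nodes, default 4, i.e. classes
#' with more than three nodes are kept) and sorts the rest by
#' [community_score()] descending; ties break by community index ascending.
#'
#' @inheritParams community_score
#' @param min_size Minimum community size retained (default 4).
#' @return A tibble of community scores, ranked.
#' @export
rank_communities <- function(graph, partition, min_size = 4,
                             resolution = partition$resolution) {
  community_scores(graph, partition, resolution) |>
    filter(.data$n_nodes >= min_size) |>
    arrange(desc(.data$score), .data$community)
}

#' Induced subgraph of one community
#'
#' @inheritParams community_score
#' @return The knowledge graph induced on the community's members (directed,
#'   as stored; centrality routines take their own views).
#' @export
community_subgraph <- function(graph, partition, community) {
  ids <- names(partition$membership)[partition$membership == community]
  if (length(ids) == 0)
    abort(paste0("No community with index ", community, "."))
  as_kg(igraph::induced_subgraph(graph, ids))
}

#' Partition stability across seeds
#'
#' Runs [louvain_partition()] under `replicates` different seeds and reports
#' the mean pairwise co-clustering agreement: the fraction of node pairs that
#' are either together in both partitions or apart in both (Rand index),
#' averaged over all partition pairs. Values near 1 indicate the class
#' structure does not depend on the randomized local-move order.
#'
#' @inheritParams louvain_partition
#' @param replicates Number of seeded replicate runs (default 10).
#' @return A one-row tibble: `replicates`, `mean_rand_index`,
#'   `n_communities_min`, `n_communities_max`.
#' @export
partition_stability <- function(graph, resolution = 1, replicates = 10,
                                seed = 1L) {
  parts <- lapply(seq_len(replicates), function(r)
    louvain_partition(graph, resolution, seed = as.integer(seed) + r - 1L))
  rand_index <- function(a, b) {
    ca <- outer(a, a, "=="); cb <- outer(b, b, "==")
    ut <- upper.tri(ca)
    mean(ca[ut] == cb[ut])
  }
  n <- length(parts)
  pairs <- utils::combn(n, 2)
  ri <- vapply(seq_len(ncol(pairs)), function(j)
    rand_index(parts[[pairs[1, j]]]$membership,
               parts[[pairs[2, j]]]$membership), numeric(1))
  tibble(replicates = replicates, mean_rand_index = mean(ri),
         n_communities_min = min(vapply(parts, `[[`, integer(1), "n_communities")),
         n_communities_max = max(vapply(parts, `[[`, integer(1), "n_communities")))
}
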
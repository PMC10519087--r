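#' Centrality computation parameters
#'
#' Defaults follow common network-toolbox settings: 100 power-iteration steps
#' for eigenvector centrality (the node ordering is insensitive to this count
#' over a wide range), PageRank damping 0.85 and an L1 convergence tolerance
#' (epsilon) of 0.001.
#'
#' @param eigenvector_iterations Power-iteration steps (>= 1).
#' @param pagerank_damping Damping probability p in (0, 1).
#' @param pagerank_epsilon Convergence tolerance (> 0) on the L1 change of
#'   the PageRank vector between sweeps.
#' @return A `centrality_config` list.
#' @export
centrality_config <- function(eigenvector_iterations = 100L,
                              pagerank_damping = 0.85,
                              pagerank_epsilon = 0.001) {
  if (eigenvector_iterations < 1) abort("`eigenvector_iterations` must be >= 1.")
  if (pagerank_damping <= 0 || pagerank_damping >= 1)
    abort("`pagerank_damping` must be in (0, 1).")
  if (pagerank_epsilon <= 0) abort("`pagerank_epsilon` must be > 0.")
  structure(list(eigenvector_iterations = as.integer(eigenvector_iterations),
                 pagerank_damping = pagerank_damping,
                 pagerank_epsilon = pagerank_epsilon),
            class = "centrality_config")
}

#' Degree centrality
#'
#' Raw degree: the number of edges connected to a node in the undirected
#' simple view (one adjacency per connected pair). Not normalized; min-max
#' rescaling happens later in the TNCS step.
#'
#' @param subgraph A knowledge graph (typically one community's subgraph).
#' @return Named numeric vector of per-node scores.
#' @export
centrality_degree <- function(subgraph) {
  u <- .kg_und_simple(subgraph)
  d <- igraph::degree(u)
  stats::setNames(as.numeric(d), igraph::V(u)$name)
}

#' Closeness centrality (Wasserman-Faust)
#'
#' Inverse average distance from a node to the nodes it can reach, scaled by
#' the fraction of the graph it reaches:
#' `C(u) = ((r - 1) / (n - 1)) * ((r - 1) / sum of distances)`, with `r` the
#' size of u's connected component. The scaling keeps scores in \[0, 1\] on
#' disconnected community subgraphs; nodes in singleton components score 0.
#'
#' @inheritParams centrality_degree
#' @export
centrality_closeness <- function(subgraph) {
  u <- .kg_und_simple(subgraph)
  n <- igraph::vcount(u)
  if (n == 1)
    return(stats::setNames(0, igraph::V(u)$name))
  d <- igraph::distances(u, mode = "all")
  scores <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r1 <- length(reach)           # component size minus one
    if (r1 == 0 || sum(reach) == 0) return(0)
    (r1 / (n - 1)) * (r1 / sum(reach))
  }, numeric(1))
  stats::setNames(scores, igraph::V(u)$name)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between every other node pair that pass
#' through the node, i.e. Brandes betweenness on the undirected simple view
#' normalized by the `(n-1)(n-2)/2` possible pairs, so scores are fractions
#' in \[0, 1\].
#'
#' @inheritParams centrality_degree
#' @export
centrality_betweenness <- function(subgraph) {
  u <- .kg_und_simple(subgraph)
  n <- igraph::vcount(u)
  if (n < 3)
    return(stats::setNames(rep(0, n), igraph::V(u)$name))
  b <- igraph::betweenness(u, directed = FALSE, normalized = TRUE)
  stats::setNames(as.numeric(b), igraph::V(u)$name)
}

#' Eigenvector centrality by fixed-count power iteration
#'
#' Runs `eigenvector_iterations` power-iteration steps of the undirected
#' adjacency matrix starting from the uniform vector, renormalizing each
#' step, and max-normalizes the result to \[0, 1\] (the most central node
#' scores exactly 1). A node's score is proportional to the sum of its
#' neighbors' scores, so influence is transitive. Numerically the iteration
#' uses the unit-shifted matrix A + I, which has the same principal
#' eigenvector as A but converges on bipartite structures (stars, paths)
#' where the unshifted iteration oscillates between the two node classes.
#' Isolated nodes score 0; an edgeless graph is an error (the measure is
#' undefined).
#'
#' @inheritParams centrality_degree
#' @param config A [centrality_config()].
#' @export
centrality_eigenvector <- function(subgraph, config = centrality_config()) {
  u <- .kg_und_simple(subgraph)
  n <- igraph::vcount(u)
  if (igraph::ecount(u) == 0)
    abort("Eigenvector centrality is undefined on an edgeless graph.")
  A <- igraph::as_adjacency_matrix(u, sparse = TRUE)
  x <- rep(1 / n, n)
  for (i in seq_len(config$eigenvector_iterations)) {
    x <- as.numeric(A %*% x) + x   # (A + I) x: damps bipartite oscillation
    nx <- max(x)
    if (nx > 0) x <- x / nx
  }
  stats::setNames(x / max(x), igraph::V(u)$name)
}

#' PageRank centrality by damped iteration
#'
#' PageRank is the eigenvector-type measure that credits a node by its
#' incoming links: computed on the directed simple view with damping `p`,
#' dangling-node mass redistributed uniformly, iterating
#' `x <- (1-p)/n + p * (A^T (x / outdeg) + dangling/n)` until the L1 change
#' drops below `pagerank_epsilon`. Scores are positive and sum to 1.
#'
#' @inheritParams centrality_eigenvector
#' @export
centrality_pagerank <- function(subgraph, config = centrality_config()) {
  g <- igraph::simplify(subgraph, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  n <- igraph::vcount(g)
  if (n == 1) return(stats::setNames(1, igraph::V(g)$name))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  outdeg <- as.numeric(Matrix::rowSums(A))
  p <- config$pagerank_damping
  x <- rep(1 / n, n)
  repeat {
    share <- ifelse(outdeg > 0, x / pmax(outdeg, 1), 0)
    dangling <- sum(x[outdeg == 0])
    x_new <- (1 - p) / n + p * (as.numeric(Matrix::crossprod(A, share)) +
                                  dangling / n)
    if (sum(abs(x_new - x)) < config$pagerank_epsilon) {
      x <- x_new
      break
    }
    x <- x_new
  }
  stats::setNames(x / sum(x), igraph::V(g)$name)
}

#' All five centralities for one community subgraph
#'
#' Computes degree, closeness, betweenness, eigenvector, and PageRank
#' centrality for every node of a community subgraph (measures are taken
#' within the community, not over the whole profile network). Degree,
#' closeness, betweenness and eigenvector use the undirected view;
#' PageRank respects edge direction.
#'
#' @inheritParams centrality_eigenvector
#' @return A `centrality_table`: tibble with columns `node_id`, `degree`,
#'   `closeness`, `betweenness`, `eigenvector`, `pagerank`.
#' @examples
#' star <- kg_graph(data.frame(node_id = c("hub", paste0("leaf", 1:4))),
#'                  data.frame(source = "hub", target = paste0("leaf", 1:4),
#'                             predicate = "related_to"))
#' compute_centralities(star)
#' @export
compute_centralities <- function(subgraph, config = centrality_config()) {
  ids <- igraph::V(subgraph)$name
  deg <- centrality_degree(subgraph)
  clo <- centrality_closeness(subgraph)
  bet <- centrality_betweenness(subgraph)
  eig <- centrality_eigenvector(subgraph, config)
  pr <- centrality_pagerank(subgraph, config)
  out <- tibble(node_id = ids,
                degree = unname(deg[ids]),
                closeness = unname(clo[ids]),
                betweenness = unname(bet[ids]),
                eigenvector = unname(eig[ids]),
                pagerank = unname(pr[ids]))
  class(out) <- c("centrality_table", class(out))
  out
}

.centrality_measures <- c("degree", "closeness", "betweenness",
                          "eigenvector", "pagerank")
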
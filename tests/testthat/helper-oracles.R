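# Brute-force oracles, written against plain adjacency matrices so they share
# no code path with the package's igraph-based routines.

# symmetric 0/1 adjacency matrix of a kg's undirected simple view,
# built directly from the edge table
und_adjacency <- function(graph) {
  ids <- igraph::V(graph)$name
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  ed <- kg_edges(graph)
  for (i in seq_len(nrow(ed))) {
    A[ed$source[i], ed$target[i]] <- 1
    A[ed$target[i], ed$source[i]] <- 1
  }
  diag(A) <- 0
  A
}

# single-source BFS hop distances on an adjacency matrix
bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] > 0 & is.infinite(d))
      d[nb] <- d[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

all_pairs_dist <- function(A) {
  t(vapply(seq_len(nrow(A)), function(s) bfs_dist(A, s), numeric(nrow(A))))
}

oracle_degree <- function(A) rowSums(A)

oracle_closeness <- function(A) {
  n <- nrow(A)
  if (n == 1) return(stats::setNames(0, rownames(A)))
  D <- all_pairs_dist(A)
  scores <- vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    reach <- di[is.finite(di)]
    if (length(reach) == 0 || sum(reach) == 0) return(0)
    (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }, numeric(1))
  stats::setNames(scores, rownames(A))
}

# shortest-path counts sigma[s, t] by dynamic programming over BFS levels
path_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || is.infinite(D[s, t])) next
      preds <- which(A[t, ] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) return(stats::setNames(rep(0, n), rownames(A)))
  D <- all_pairs_dist(A)
  sigma <- path_counts(A, D)
  b <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    if (is.infinite(D[s, t]) || sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  stats::setNames(b / ((n - 1) * (n - 2) / 2), rownames(A))
}

oracle_eigenvector <- function(A) {
  ev <- eigen(A, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  stats::setNames(v / max(v), rownames(A))
}

# exact damped PageRank with uniform dangling redistribution, by solving the
# fixed-point linear system
oracle_pagerank <- function(A_directed, p = 0.85) {
  n <- nrow(A_directed)
  outdeg <- rowSums(A_directed)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (outdeg[i] > 0) P[, i] <- A_directed[i, ] / outdeg[i]
    else P[, i] <- 1 / n
  }
  x <- solve(diag(n) - p * P, rep((1 - p) / n, n))
  stats::setNames(x / sum(x), rownames(A_directed))
}

# PageRank oracle on the adjacency that matches the graph's directedness
pagerank_oracle_for <- function(graph, p = 0.85) {
  A <- if (igraph::is_directed(graph)) dir_adjacency(graph)
       else und_adjacency(graph)
  oracle_pagerank(A, p)
}

# directed 0/1 adjacency from the edge table
dir_adjacency <- function(graph) {
  ids <- igraph::V(graph)$name
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ed <- kg_edges(graph)
  for (i in seq_len(nrow(ed))) A[ed$source[i], ed$target[i]] <- 1
  diag(A) <- 0
  A
}
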
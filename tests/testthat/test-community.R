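# Newman modularity from the membership and adjacency alone (no igraph)
modularity_oracle <- function(A, memb, gamma = 1) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (c in unique(memb)) {
    idx <- which(memb == c)
    L_c <- sum(A[idx, idx]) / 2
    k_c <- sum(deg[idx])
    q <- q + L_c / m - gamma * (k_c / (2 * m))^2
  }
  q
}

test_that("an edgeless graph partitions into singletons", {
  g <- kg_graph(node_tbl(paste0("v", 1:5)))
  part <- louvain_partition(g)
  expect_equal(part$n_communities, 5)
  expect_setequal(unname(part$membership), 0:4)
})

test_that("two joined cliques are split into the two cliques", {
  g <- two_cliques_kg(5)
  part <- louvain_partition(g, seed = 1)
  expect_equal(part$n_communities, 2)
  memb <- part$membership
  expect_length(unique(memb[paste0("x", 1:5)]), 1)
  expect_length(unique(memb[paste0("y", 1:5)]), 1)
})

test_that("Louvain attains the exhaustive-search optimum on two triangles", {
  # all set partitions of 6 nodes, scored by the modularity oracle
  g <- kg_graph(node_tbl(paste0("v", 1:6)),
                rbind(edge_tbl(c("v1", "v2", "v1"), c("v2", "v3", "v3")),
                      edge_tbl(c("v4", "v5", "v4"), c("v5", "v6", "v6")),
                      edge_tbl("v3", "v4")),
                directed = FALSE)
  A <- und_adjacency(g)
  partitions_of <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (p in partitions_of(n - 1)) {
      for (b in seq_len(max(p) + 1)) out[[length(out) + 1]] <- c(p, b)
    }
    out
  }
  best <- -Inf
  best_p <- NULL
  for (p in partitions_of(6)) {
    q <- modularity_oracle(A, p)
    if (q > best) { best <- q; best_p <- p }
  }
  # the optimum is the two triangles
  expect_length(unique(best_p[1:3]), 1)
  expect_length(unique(best_p[4:6]), 1)
  expect_false(best_p[1] == best_p[4])

  part <- louvain_partition(g, seed = 3)
  q_louvain <- modularity_oracle(A, unname(part$membership[rownames(A)]) + 1)
  expect_equal(q_louvain, best, tolerance = 1e-12)
})

test_that("louvain is deterministic given a seed and rejects empty graphs", {
  sim <- generate_kg(small_synth_config(seed = 40))
  p1 <- louvain_partition(sim$graph, seed = 5)
  p2 <- louvain_partition(sim$graph, seed = 5)
  expect_identical(p1$membership, p2$membership)
  expect_error(louvain_partition(kg_graph(node_tbl(character(0)))), "empty")

  # completeness: every node in exactly one community, indices from 0
  expect_setequal(names(p1$membership), kg_nodes(sim$graph)$node_id)
  expect_equal(sort(unique(unname(p1$membership))),
               0:(p1$n_communities - 1))
})

test_that("the community score follows the formula exactly", {
  # whole graph as one community at gamma = 1: L_c = m, k_c = 2m, score 0
  g <- two_cliques_kg(5)
  part <- structure(list(membership = stats::setNames(
    rep(0L, igraph::vcount(g)), igraph::V(g)$name),
    n_communities = 1L, resolution = 1, seed = 1L), class = "kg_partition")
  s <- community_score(g, part, 0)
  expect_equal(s$score, 0)
  expect_equal(s$L_c, s$m)
  expect_equal(s$k_c, 2 * s$m)

  # two disconnected 5-cliques, each its own community: 1/2 - (1/2)^2 = 0.25
  ids <- c(paste0("x", 1:5), paste0("y", 1:5))
  pr_x <- utils::combn(paste0("x", 1:5), 2)
  pr_y <- utils::combn(paste0("y", 1:5), 2)
  g2 <- kg_graph(node_tbl(ids),
                 rbind(edge_tbl(pr_x[1, ], pr_x[2, ]),
                       edge_tbl(pr_y[1, ], pr_y[2, ])),
                 directed = FALSE)
  part2 <- structure(list(membership = stats::setNames(
    rep(0:1, each = 5), ids), n_communities = 2L, resolution = 1, seed = 1L),
    class = "kg_partition")
  # each clique: L_c = 10 of m = 20 edges, k_c = 5 * 4 = 20,
  # so score = 10/20 - (20/40)^2 = 0.25
  sc <- community_scores(g2, part2)
  expect_equal(sc$score, c(0.25, 0.25))
  expect_equal(sc$L_c, c(10, 10))
  expect_equal(sc$k_c, c(20, 20))
  expect_true(all(sc$k_c >= 2 * sc$L_c))

  # a singleton community with no internal edges scores <= 0
  g3 <- kg_graph(node_tbl(c("a", "b", "c")),
                 edge_tbl(c("a", "b"), c("b", "c")), directed = FALSE)
  part3 <- structure(list(membership = stats::setNames(c(0L, 0L, 1L),
                                                       c("a", "b", "c")),
                          n_communities = 2L, resolution = 1, seed = 1L),
                     class = "kg_partition")
  expect_lte(community_score(g3, part3, 1)$score, 0)
  expect_error(community_score(kg_graph(node_tbl(c("a", "b"))), part3, 0),
               "no edges")
})

test_that("summed community scores equal independent Newman modularity", {
  for (seed in 1:20) {
    withr::local_seed(600 + seed)
    g <- random_connected_kg(sample(10:40, 1), 0.15, seed + 700)
    n <- igraph::vcount(g)
    memb <- stats::setNames(sample(0:3, n, replace = TRUE) |> as.integer(),
                            igraph::V(g)$name)
    memb <- stats::setNames(as.integer(match(memb, unique(memb))) - 1L,
                            names(memb))
    part <- structure(list(membership = memb,
                           n_communities = length(unique(memb)),
                           resolution = 1, seed = 1L),
                      class = "kg_partition")
    total <- sum(community_scores(g, part)$score)
    A <- und_adjacency(g)
    expect_equal(total, modularity_oracle(A, unname(memb[rownames(A)]) + 1),
                 tolerance = 1e-12)
    # and against igraph's implementation as a second, library oracle
    u <- profnet:::.kg_und_simple(g)
    expect_equal(total,
                 igraph::modularity(u, memb[igraph::V(u)$name] + 1L),
                 tolerance = 1e-12)
  }
})

test_that("Louvain modularity is at least that of the singleton partition", {
  sim <- generate_kg(small_synth_config(seed = 44))
  g <- sim$graph
  part <- louvain_partition(g, seed = 2)
  singletons <- structure(list(
    membership = stats::setNames(seq_len(igraph::vcount(g)) - 1L,
                                 igraph::V(g)$name),
    n_communities = igraph::vcount(g), resolution = 1, seed = 1L),
    class = "kg_partition")
  expect_gte(sum(community_scores(g, part)$score),
             sum(community_scores(g, singletons)$score))
})

test_that("community ranking filters small classes and breaks ties by index", {
  # all singletons -> nothing to rank
  g <- kg_graph(node_tbl(paste0("v", 1:4)),
                edge_tbl(c("v1", "v3"), c("v2", "v4")), directed = FALSE)
  part <- structure(list(membership = stats::setNames(c(0L, 0L, 1L, 1L),
                                                      paste0("v", 1:4)),
                         n_communities = 2L, resolution = 1, seed = 1L),
                    class = "kg_partition")
  expect_equal(nrow(rank_communities(g, part)), 0)

  # two equal cliques tie; the lower index comes first
  g2 <- two_cliques_kg(5)
  part2 <- louvain_partition(g2, seed = 1)
  ranked <- rank_communities(g2, part2)
  expect_equal(ranked$community, sort(ranked$community))
  expect_equal(ranked$score[1], ranked$score[2])

  # a 3-community synthetic graph ranks by independently recomputed scores
  sim <- generate_kg(small_synth_config(seed = 46))
  part3 <- louvain_partition(sim$graph, seed = 1)
  ranked3 <- rank_communities(sim$graph, part3)
  A <- und_adjacency(sim$graph)
  deg <- rowSums(A); m <- sum(A) / 2
  expected <- vapply(ranked3$community, function(cm) {
    idx <- which(unname(part3$membership[rownames(A)]) == cm)
    sum(A[idx, idx]) / 2 / m - (sum(deg[idx]) / (2 * m))^2
  }, numeric(1))
  expect_equal(ranked3$score, expected, tolerance = 1e-12)
  expect_false(is.unsorted(rev(ranked3$score)))
})

test_that("partition stability reports near-perfect agreement on clean structure", {
  g <- two_cliques_kg(6)
  st <- partition_stability(g, replicates = 5, seed = 1)
  expect_gte(st$mean_rand_index, 0.99)
})
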
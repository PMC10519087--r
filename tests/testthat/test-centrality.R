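test_that("degree, closeness, betweenness behave on canonical small graphs", {
  star <- star_kg(6)
  expect_equal(unname(centrality_degree(star)["hub"]), 6)
  expect_equal(unname(centrality_closeness(star)["hub"]), 1)

  tri <- kg_graph(node_tbl(c("a", "b", "c")),
                  edge_tbl(c("a", "b", "c"), c("b", "c", "a")),
                  directed = FALSE)
  expect_equal(unname(centrality_degree(tri)), rep(2, 3))

  iso <- kg_graph(node_tbl(c("a", "b", "c")), edge_tbl("a", "b"),
                  directed = FALSE)
  expect_equal(unname(centrality_degree(iso)["c"]), 0)

  p3 <- path_kg(3)
  clo <- centrality_closeness(p3)
  expect_equal(unname(clo["v2"]), 1)
  expect_equal(unname(clo[c("v1", "v3")]), c(2 / 3, 2 / 3))
  bet <- centrality_betweenness(p3)
  expect_equal(unname(bet["v2"]), 1)  # on the only other pair's path
  expect_equal(unname(bet[c("v1", "v3")]), c(0, 0))
})

test_that("eigenvector centrality is symmetric on cycles and maximal at hubs", {
  cyc <- kg_graph(node_tbl(paste0("c", 1:6)),
                  edge_tbl(paste0("c", 1:6), paste0("c", c(2:6, 1))),
                  directed = FALSE)
  ev <- centrality_eigenvector(cyc)
  expect_equal(unname(ev), rep(1, 6))

  star <- star_kg(8)
  evs <- centrality_eigenvector(star)
  expect_equal(unname(evs["hub"]), 1)
  expect_true(all(evs[paste0("leaf", 1:8)] < 1))

  expect_error(centrality_eigenvector(kg_graph(node_tbl(c("a", "b")))),
               "edgeless")
})

test_that("eigenvector node ordering is insensitive to the iteration count", {
  for (seed in 1:5) {
    g <- random_connected_kg(20, 0.15, seed + 40)
    o50 <- order(centrality_eigenvector(g, centrality_config(eigenvector_iterations = 50)))
    o200 <- order(centrality_eigenvector(g, centrality_config(eigenvector_iterations = 200)))
    expect_equal(o50, o200)
  }
})

test_that("pagerank is uniform on regular strongly-connected graphs and sums to 1", {
  cyc <- kg_graph(node_tbl(paste0("c", 1:5)),
                  edge_tbl(paste0("c", 1:5), paste0("c", c(2:5, 1))),
                  directed = TRUE)
  pr <- centrality_pagerank(cyc)
  expect_equal(unname(pr), rep(0.2, 5), tolerance = 1e-3)

  for (seed in 1:5) {
    g <- random_connected_kg(15, 0.2, seed + 50)
    expect_equal(sum(centrality_pagerank(g)), 1, tolerance = 1e-9)
  }
})

test_that("pagerank matches the exact fixed point on a 3-node chain", {
  chain <- kg_graph(node_tbl(c("A", "B", "C")),
                    edge_tbl(c("A", "B"), c("B", "C")), directed = TRUE)
  pr <- centrality_pagerank(chain)
  A <- dir_adjacency(chain)
  exact <- oracle_pagerank(A)
  expect_equal(unname(pr[rownames(A)]), unname(exact), tolerance = 0.01)
})

test_that("all five measures agree with brute-force oracles on random graphs", {
  cfg <- centrality_config()
  for (seed in 1:8) {
    g <- random_connected_kg(sample(8:25, 1), 0.2, seed + 60)
    A <- und_adjacency(g)
    ids <- rownames(A)
    expect_equal(centrality_degree(g)[ids], oracle_degree(A))
    expect_equal(centrality_closeness(g)[ids], oracle_closeness(A),
                 tolerance = 1e-12)
    expect_equal(centrality_betweenness(g)[ids], oracle_betweenness(A),
                 tolerance = 1e-10)
    expect_equal(centrality_eigenvector(g, cfg)[ids], oracle_eigenvector(A),
                 tolerance = 1e-3)
    expect_equal(centrality_pagerank(g, cfg)[ids],
                 oracle_pagerank(dir_adjacency(g)), tolerance = 0.01)
  }
})

test_that("closeness stays within [0, 1] on disconnected subgraphs", {
  g <- kg_graph(node_tbl(paste0("v", 1:7)),
                rbind(edge_tbl(c("v1", "v2", "v3"), c("v2", "v3", "v4")),
                      edge_tbl("v5", "v6")),
                directed = FALSE)
  clo <- centrality_closeness(g)
  expect_true(all(clo >= 0 & clo <= 1))
  expect_equal(unname(clo["v7"]), 0)
  A <- und_adjacency(g)
  expect_equal(clo[rownames(A)], oracle_closeness(A), tolerance = 1e-12)
})

test_that("compute_centralities returns the full five-measure table", {
  one_edge <- kg_graph(node_tbl(c("a", "b")), edge_tbl("a", "b"),
                       directed = FALSE)
  tab <- compute_centralities(one_edge)
  expect_equal(dim(tab), c(2, 6))
  expect_true(all(c("degree", "closeness", "betweenness", "eigenvector",
                    "pagerank") %in% names(tab)))

  star <- star_kg(7)
  tabs <- compute_centralities(star)
  hub_row <- tabs[tabs$node_id == "hub", ]
  for (ms in c("degree", "closeness", "betweenness", "eigenvector", "pagerank"))
    expect_equal(which.max(tabs[[ms]]), which(tabs$node_id == "hub"))
  expect_true(all(tabs$closeness >= 0 & tabs$closeness <= 1))
  expect_true(all(tabs$eigenvector >= 0 & tabs$eigenvector <= 1))
  expect_true(all(tabs$pagerank >= 0 & tabs$pagerank <= 1))
})

test_that("betweenness is computed within the community, not globally", {
  # two blobs bridged via b; inside one community the bridge role vanishes
  g <- kg_graph(node_tbl(c("a1", "a2", "a3", "b", "c1", "c2", "c3")),
                rbind(edge_tbl(c("a1", "a2", "a1"), c("a2", "a3", "a3")),
                      edge_tbl("a3", "b"), edge_tbl("b", "c1"),
                      edge_tbl(c("c1", "c2", "c1"), c("c2", "c3", "c3"))),
                directed = FALSE)
  full <- centrality_betweenness(g)
  part <- structure(list(membership = stats::setNames(
    c(0L, 0L, 0L, 0L, 1L, 1L, 1L), igraph::V(g)$name),
    n_communities = 2L, resolution = 1, seed = 1L), class = "kg_partition")
  within <- centrality_betweenness(community_subgraph(g, part, 0))
  # a3 brokers 8 of 15 pairs globally but 2 of 3 pairs inside its community
  expect_equal(unname(full["a3"]), 8 / 15)
  expect_equal(unname(within["a3"]), 2 / 3)
})
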
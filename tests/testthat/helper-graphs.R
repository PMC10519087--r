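# Small graph builders used across tests.

edge_tbl <- function(source, target, predicate = "related_to") {
  data.frame(source = source, target = target, predicate = predicate,
             stringsAsFactors = FALSE)
}

node_tbl <- function(ids, ...) {
  data.frame(node_id = ids, ..., stringsAsFactors = FALSE)
}

# undirected star: one hub, k leaves
star_kg <- function(k = 10, directed = FALSE) {
  kg_graph(node_tbl(c("hub", paste0("leaf", seq_len(k)))),
           edge_tbl("hub", paste0("leaf", seq_len(k))),
           directed = directed)
}

# simple path v1 - v2 - ... - vn
path_kg <- function(n, directed = FALSE) {
  ids <- paste0("v", seq_len(n))
  kg_graph(node_tbl(ids), edge_tbl(ids[-n], ids[-1]), directed = directed)
}

# G(n, p) knowledge graph; regenerates until the undirected view is connected
random_connected_kg <- function(n, p, seed, directed = TRUE) {
  withr::local_seed(seed)
  ids <- paste0("n", seq_len(n))
  repeat {
    pr <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pr)) < p
    if (!any(keep)) next
    flip <- stats::runif(sum(keep)) < 0.5
    a <- pr[1, keep]; b <- pr[2, keep]
    s <- ifelse(flip, b, a); t <- ifelse(flip, a, b)
    g <- kg_graph(node_tbl(ids), edge_tbl(ids[s], ids[t]),
                  directed = directed)
    if (igraph::is_connected(kg_undirected(g), mode = "weak")) return(g)
  }
}

# kg wrapper around an arbitrary undirected igraph (e.g. from the graph atlas)
kg_from_igraph_structure <- function(ig) {
  n <- igraph::vcount(ig)
  ids <- paste0("a", seq_len(n))
  el <- igraph::as_edgelist(ig, names = FALSE)
  edges <- if (nrow(el)) edge_tbl(ids[el[, 1]], ids[el[, 2]]) else NULL
  kg_graph(node_tbl(ids), edges, directed = FALSE)
}

# two k-cliques joined by a single bridge edge
two_cliques_kg <- function(size = 5) {
  ids <- c(paste0("x", seq_len(size)), paste0("y", seq_len(size)))
  clique_edges <- function(v) {
    pr <- utils::combn(v, 2)
    edge_tbl(pr[1, ], pr[2, ])
  }
  kg_graph(node_tbl(ids),
           rbind(clique_edges(ids[seq_len(size)]),
                 clique_edges(ids[size + seq_len(size)]),
                 edge_tbl("x1", "y1")),
           directed = FALSE)
}

# a small config so synthetic-graph tests stay fast
small_synth_config <- function(seed = 1L, ...) {
  args <- list(n_diseases = 30, n_genes = 20, n_drugs = 10, n_phenotypes = 10,
               n_communities = 3, p_in = 0.3, p_out = 0.02,
               n_seed_diseases = 5, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

expect_same_kg <- function(a, b) {
  na <- kg_nodes(a); nb <- kg_nodes(b)
  na <- na[order(na$node_id), ]; nb <- nb[order(nb$node_id), ]
  expect_equal(na$node_id, nb$node_id)
  expect_equal(na$primary_label, nb$primary_label)
  expect_equal(na$category, nb$category)
  expect_equal(lapply(na$synonyms, sort), lapply(nb$synonyms, sort))
  expect_equal(lapply(na$alt_labels, sort), lapply(nb$alt_labels, sort))
  expect_equal(lapply(na$external_codes, sort), lapply(nb$external_codes, sort))
  key <- function(g) {
    ed <- kg_edges(g)
    sort(paste(ed$source, ed$target, ed$predicate))
  }
  expect_equal(key(a), key(b))
}
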
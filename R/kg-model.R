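#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn inform .data %||%
#' @importFrom purrr map map_chr map_int map_dfr
NULL

# separator used to pack multi-valued node attributes into scalar graph
# attributes; must not occur inside labels/synonyms/codes
.kg_sep <- "|"

.kg_categories <- c("disease", "gene", "drug", "phenotype", "other")

#' Equivalence predicates that trigger node contraction
#'
#' Cross-resource knowledge graphs link records that denote the same concept
#' with dedicated edge types: `N_Name` (same concept name), `I_CODE` (shared
#' external reference code), and predicates adopted from source ontologies
#' such as `R_equivalentClass` and `R_exactMatch`. Edges with these predicates
#' mark node sets that [contract_kg()] merges into single concepts.
#'
#' @return Character vector of the four default equivalence predicate names.
#' @export
kg_equivalence_predicates <- function() {
  c("N_Name", "I_CODE", "R_equivalentClass", "R_exactMatch")
}

.pack <- function(x) {
  if (is.list(x)) {
    vapply(x, function(v) paste(unique(as.character(v[!is.na(v) & nzchar(v)])),
                                collapse = .kg_sep), character(1))
  } else {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }
}

.unpack <- function(x) {
  lapply(as.character(x), function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, .kg_sep, fixed = TRUE)[[1]]
  })
}

#' Construct a biomedical knowledge graph
#'
#' Builds a directed, typed multigraph of biomedical concepts from a node
#' table and an edge table. Nodes carry a primary label, alternative labels,
#' a category (`disease`, `gene`, `drug`, `phenotype`, `other`), a source
#' resource, synonyms, and external codes (e.g. `"OMIM:254780"`). Edges carry
#' a predicate; parallel edges between the same pair are permitted only with
#' distinct predicates, and self-loops are rejected.
#'
#' @param nodes Data frame with column `node_id` (unique, non-empty) and
#'   optional columns `primary_label`, `alt_labels`, `category`,
#'   `source_resource`, `synonyms`, `external_codes`. Multi-valued columns may
#'   be list-columns or `"|"`-delimited strings. Missing optional fields
#'   default to empty; `primary_label` defaults to `node_id`.
#' @param edges Data frame with columns `source`, `target`, `predicate`
#'   (all referencing existing `node_id`s; predicate non-empty), or `NULL`
#'   for an edgeless graph.
#' @param directed Store edge direction (default `TRUE`).
#' @return A knowledge graph: an [igraph::igraph] object of class `kg`.
#' @examples
#' g <- kg_graph(
#'   data.frame(node_id = c("GARD:1", "HGNC:2"),
#'              category = c("disease", "gene")),
#'   data.frame(source = "GARD:1", target = "HGNC:2",
#'              predicate = "associated_with")
#' )
#' kg_nodes(g)
#' @export
kg_graph <- function(nodes, edges = NULL, directed = TRUE) {
  nodes <- as_tibble(nodes)
  if (!"node_id" %in% names(nodes)) abort("`nodes` must have a `node_id` column.")
  nodes$node_id <- as.character(nodes$node_id)
  if (anyNA(nodes$node_id) || any(!nzchar(nodes$node_id)))
    abort("`node_id` must be non-empty.")
  if (anyDuplicated(nodes$node_id)) {
    dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
    abort(paste0("Duplicate node_id: ", paste(dup, collapse = ", ")))
  }

  lab <- as.character(nodes[["primary_label"]] %||% nodes$node_id)
  lab[is.na(lab) | !nzchar(lab)] <- nodes$node_id[is.na(lab) | !nzchar(lab)]
  cat <- as.character(nodes[["category"]] %||% rep("other", nrow(nodes)))
  cat[is.na(cat) | !nzchar(cat)] <- "other"
  # a merged node may carry a packed set of member categories
  unknown <- !vapply(strsplit(cat, .kg_sep, fixed = TRUE),
                     function(p) all(p %in% .kg_categories), logical(1))
  if (any(unknown)) {
    warn(paste0("Unknown category mapped to \"other\": ",
                paste(unique(cat[unknown]), collapse = ", ")))
    cat[unknown] <- "other"
  }

  vat <- tibble(
    name = nodes$node_id,
    primary_label = lab,
    category = cat,
    source_resource = .pack(nodes[["source_resource"]] %||% rep("", nrow(nodes))),
    alt_labels = .pack(nodes[["alt_labels"]] %||% rep("", nrow(nodes))),
    synonyms = .pack(nodes[["synonyms"]] %||% rep("", nrow(nodes))),
    external_codes = .pack(nodes[["external_codes"]] %||% rep("", nrow(nodes)))
  )

  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    eat <- tibble(source = character(0), target = character(0),
                  predicate = character(0))
  } else {
    edges <- as_tibble(edges)
    need <- c("source", "target", "predicate")
    if (!all(need %in% names(edges)))
      abort("`edges` must have columns source, target, predicate.")
    eat <- tibble(source = as.character(edges$source),
                  target = as.character(edges$target),
                  predicate = as.character(edges$predicate))
    if (any(is.na(eat$predicate) | !nzchar(eat$predicate)))
      abort("Edge predicates must be non-empty.")
    missing <- setdiff(c(eat$source, eat$target), vat$name)
    if (length(missing))
      abort(paste0("Edge endpoint not in node table: ",
                   paste(unique(missing), collapse = ", ")))
    if (any(eat$source == eat$target))
      abort("Self-loop edges are not allowed on input.")
    dup <- duplicated(eat[c("source", "target", "predicate")])
    if (any(dup)) eat <- eat[!dup, ]
  }

  g <- igraph::graph_from_data_frame(
    d = data.frame(from = eat$source, to = eat$target,
                   predicate = eat$predicate, stringsAsFactors = FALSE),
    directed = directed,
    vertices = as.data.frame(vat)
  )
  as_kg(g)
}

#' Mark an igraph object as a knowledge graph
#' @param g An igraph object with `kg` vertex/edge attributes.
#' @return The same graph with class `kg` prepended.
#' @keywords internal
#' @export
as_kg <- function(g) {
  class(g) <- unique(c("kg", class(g)))
  g
}

#' Node table of a knowledge graph
#'
#' @param graph A knowledge graph from [kg_graph()].
#' @return A tibble with one row per concept: `node_id`, `primary_label`,
#'   `category`, `source_resource`, and list-columns `alt_labels`, `synonyms`,
#'   `external_codes`.
#' @export
kg_nodes <- function(graph) {
  v <- igraph::vertex_attr(graph)
  tibble(
    node_id = v$name,
    primary_label = v$primary_label %||% v$name,
    category = v$category %||% rep("other", length(v$name)),
    source_resource = v$source_resource %||% rep("", length(v$name)),
    alt_labels = .unpack(v$alt_labels %||% rep("", length(v$name))),
    synonyms = .unpack(v$synonyms %||% rep("", length(v$name))),
    external_codes = .unpack(v$external_codes %||% rep("", length(v$name)))
  )
}

#' Edge table of a knowledge graph
#'
#' @inheritParams kg_nodes
#' @return A tibble with columns `source`, `target`, `predicate`.
#' @export
kg_edges <- function(graph) {
  if (igraph::ecount(graph) == 0)
    return(tibble(source = character(0), target = character(0),
                  predicate = character(0)))
  el <- igraph::as_edgelist(graph, names = TRUE)
  tibble(source = el[, 1], target = el[, 2],
         predicate = igraph::edge_attr(graph, "predicate") %||%
           rep("", nrow(el)))
}

#' Undirected view of a knowledge graph
#'
#' Collapses each directed edge to one undirected adjacency; reciprocal
#' directed pairs and parallel edges collapse to a single adjacency whose
#' `predicate` attribute concatenates the distinct predicates, preserving
#' multiplicity as metadata. Ego extraction, Louvain clustering, and four of
#' the five centralities operate on this view.
#'
#' @inheritParams kg_nodes
#' @return An undirected knowledge graph.
#' @export
kg_undirected <- function(graph) {
  if (!igraph::is_directed(graph)) return(as_kg(graph))
  u <- igraph::as_undirected(
    graph, mode = "collapse",
    edge.attr.comb = list(predicate = function(x)
      paste(unique(x), collapse = .kg_sep))
  )
  as_kg(u)
}

# simple undirected view: one unweighted adjacency per connected pair,
# no loops -- the graph all community/centrality arithmetic runs on
.kg_und_simple <- function(graph) {
  u <- kg_undirected(graph)
  igraph::simplify(u, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(predicate = function(x)
                     paste(unique(x), collapse = .kg_sep)))
}

#' Whole-graph network properties
#'
#' Computes the summary statistics conventionally reported for a profile
#' network: node and edge counts, average degree defined as edges per node
#' (E/N), directed density E/(N(N-1)), and the diameter and average path
#' length in hops. Path-based statistics are computed over the largest
#' connected component of the undirected view; when the graph is disconnected
#' the component used is reported via a message.
#'
#' @inheritParams kg_nodes
#' @return A one-row tibble: `n_nodes`, `n_edges`, `average_degree`,
#'   `diameter`, `average_path_length`, `density`, `n_components`,
#'   `lcc_n_nodes`.
#' @export
kg_stats <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) abort("Cannot compute statistics of an empty graph.")
  e <- igraph::ecount(graph)
  u <- .kg_und_simple(graph)
  comp <- igraph::components(u)
  if (comp$no > 1)
    inform(paste0("Graph has ", comp$no, " components; diameter and average ",
                  "path length computed on the largest (",
                  max(comp$csize), " nodes)."))
  lcc <- igraph::induced_subgraph(u, which(comp$membership == which.max(comp$csize)))
  if (igraph::vcount(lcc) > 1) {
    diam <- igraph::diameter(lcc, directed = FALSE, unconnected = FALSE)
    apl <- igraph::mean_distance(lcc, directed = FALSE)
  } else {
    diam <- 0
    apl <- NA_real_
  }
  tibble(
    n_nodes = n,
    n_edges = e,
    average_degree = e / n,
    diameter = as.numeric(diam),
    average_path_length = apl,
    density = if (n > 1) e / (n * (n - 1)) else 0,
    n_components = comp$no,
    lcc_n_nodes = max(comp$csize)
  )
}
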
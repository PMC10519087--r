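#' Read a knowledge graph from file
#'
#' Supported formats: GraphML (via igraph), GEXF 1.2, and a TSV edge list
#' (`source<TAB>target<TAB>predicate` with header) accompanied by a sidecar
#' JSON node table keyed by `node_id` (same path with extension
#' `.nodes.json`). All node fields and edge predicates round-trip losslessly
#' through [write_kg()].
#'
#' @param path File path.
#' @param format One of `"graphml"`, `"gexf"`, `"tsv"`. Default guesses from
#'   the file extension.
#' @return A knowledge graph (see [kg_graph()]).
#' @export
read_kg <- function(path, format = c("auto", "graphml", "gexf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  switch(format,
    graphml = .read_graphml(path),
    gexf = .read_gexf(path),
    tsv = .read_tsv_kg(path)
  )
}

#' Write a knowledge graph to file
#'
#' @param graph A knowledge graph.
#' @inheritParams read_kg
#' @return `path`, invisibly.
#' @export
write_kg <- function(graph, path, format = c("auto", "graphml", "gexf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  switch(format,
    graphml = igraph::write_graph(graph, path, format = "graphml"),
    gexf = .write_gexf(graph, path),
    tsv = .write_tsv_kg(graph, path)
  )
  invisible(path)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    graphml = "graphml",
    gexf = "gexf",
    tsv = "tsv",
    txt = "tsv",
    abort(paste0("Cannot guess graph format from extension \".", ext,
                 "\"; pass `format` explicitly."))
  )
}

.kg_from_igraph <- function(g) {
  v <- igraph::vertex_attr(g)
  ids <- v$name %||% v$id %||% as.character(seq_len(igraph::vcount(g)))
  nodes <- tibble(
    node_id = as.character(ids),
    primary_label = as.character(v$primary_label %||% v$label %||% ids),
    category = as.character(v$category %||% rep("other", length(ids))),
    source_resource = as.character(v$source_resource %||% rep("", length(ids))),
    alt_labels = as.character(v$alt_labels %||% rep("", length(ids))),
    synonyms = as.character(v$synonyms %||% rep("", length(ids))),
    external_codes = as.character(v$external_codes %||% rep("", length(ids)))
  )
  edges <- NULL
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- tibble(
      source = nodes$node_id[el[, 1]],
      target = nodes$node_id[el[, 2]],
      predicate = as.character(igraph::edge_attr(g, "predicate") %||%
                                 rep("related_to", nrow(el)))
    )
  }
  kg_graph(nodes, edges, directed = igraph::is_directed(g))
}

.read_graphml <- function(path) {
  g <- tryCatch(
    igraph::read_graph(path, format = "graphml"),
    error = function(e) abort(paste0("Malformed GraphML in ", path, ": ",
                                     conditionMessage(e)))
  )
  .kg_from_igraph(g)
}

# --- GEXF 1.2 ---------------------------------------------------------------
# Minimal GEXF serialization: node attvalues hold the concept fields, the
# edge `label` holds the predicate.

.gexf_fields <- c("category", "source_resource", "alt_labels", "synonyms",
                  "external_codes")

.write_gexf <- function(graph, path) {
  nd <- kg_nodes(graph)
  ed <- kg_edges(graph)
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  gr <- xml2::xml_add_child(
    doc, "graph",
    defaultedgetype = if (igraph::is_directed(graph)) "directed" else "undirected")
  attrs <- xml2::xml_add_child(gr, "attributes", class = "node")
  for (i in seq_along(.gexf_fields))
    xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1),
                        title = .gexf_fields[i], type = "string")
  nodes_el <- xml2::xml_add_child(gr, "nodes")
  packed <- list(category = nd$category, source_resource = nd$source_resource,
                 alt_labels = .pack(nd$alt_labels),
                 synonyms = .pack(nd$synonyms),
                 external_codes = .pack(nd$external_codes))
  for (i in seq_len(nrow(nd))) {
    n_el <- xml2::xml_add_child(nodes_el, "node", id = nd$node_id[i],
                                label = nd$primary_label[i])
    av <- xml2::xml_add_child(n_el, "attvalues")
    for (j in seq_along(.gexf_fields))
      xml2::xml_add_child(av, "attvalue", `for` = as.character(j - 1),
                          value = packed[[.gexf_fields[j]]][i])
  }
  edges_el <- xml2::xml_add_child(gr, "edges")
  for (i in seq_len(nrow(ed)))
    xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1),
                        source = ed$source[i], target = ed$target[i],
                        label = ed$predicate[i])
  xml2::write_xml(doc, path)
  invisible(path)
}

.read_gexf <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("Malformed GEXF in ", path,
                                                   ": ", conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  attr_titles <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//attributes[@class='node']/attribute"), "title")
  names(attr_titles) <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//attributes[@class='node']/attribute"), "id")
  node_els <- xml2::xml_find_all(doc, ".//nodes/node")
  nodes <- map_dfr(node_els, function(n) {
    avs <- xml2::xml_find_all(n, ".//attvalue")
    vals <- stats::setNames(xml2::xml_attr(avs, "value"),
                            attr_titles[xml2::xml_attr(avs, "for")])
    tibble(node_id = xml2::xml_attr(n, "id"),
           primary_label = xml2::xml_attr(n, "label"),
           category = vals[["category"]] %||% "other",
           source_resource = vals[["source_resource"]] %||% "",
           alt_labels = vals[["alt_labels"]] %||% "",
           synonyms = vals[["synonyms"]] %||% "",
           external_codes = vals[["external_codes"]] %||% "")
  })
  if (nrow(nodes) == 0)
    nodes <- tibble(node_id = character(0))
  edge_els <- xml2::xml_find_all(doc, ".//edges/edge")
  edges <- NULL
  if (length(edge_els) > 0)
    edges <- tibble(source = xml2::xml_attr(edge_els, "source"),
                    target = xml2::xml_attr(edge_els, "target"),
                    predicate = xml2::xml_attr(edge_els, "label"))
  directed <- identical(
    xml2::xml_attr(xml2::xml_find_first(doc, ".//graph"), "defaultedgetype"),
    "directed")
  kg_graph(nodes, edges, directed = directed)
}

# --- TSV edge list + JSON node table ----------------------------------------

.tsv_sidecar <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".nodes.json")
}

.write_tsv_kg <- function(graph, path) {
  ed <- kg_edges(graph)
  utils::write.table(as.data.frame(ed), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  nd <- kg_nodes(graph)
  node_map <- stats::setNames(
    lapply(seq_len(nrow(nd)), function(i) list(
      primary_label = nd$primary_label[i],
      category = nd$category[i],
      source_resource = nd$source_resource[i],
      alt_labels = as.list(nd$alt_labels[[i]]),
      synonyms = as.list(nd$synonyms[[i]]),
      external_codes = as.list(nd$external_codes[[i]])
    )),
    nd$node_id)
  jsonlite::write_json(node_map, .tsv_sidecar(path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

.read_tsv_kg <- function(path) {
  ed <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("source", "target", "predicate")
  if (!all(need %in% names(ed)))
    abort(paste0("TSV edge list ", path,
                 " must have header source<TAB>target<TAB>predicate."))
  side <- .tsv_sidecar(path)
  if (!file.exists(side))
    abort(paste0("Node table not found: ", side))
  node_map <- jsonlite::read_json(side)
  flat <- function(x) unlist(x) %||% character(0)
  nodes <- tibble(
    node_id = names(node_map),
    primary_label = map_chr(node_map, ~ .x$primary_label %||% ""),
    category = map_chr(node_map, ~ .x$category %||% "other"),
    source_resource = map_chr(node_map, ~ .x$source_resource %||% ""),
    alt_labels = map(node_map, ~ flat(.x$alt_labels)),
    synonyms = map(node_map, ~ flat(.x$synonyms)),
    external_codes = map(node_map, ~ flat(.x$external_codes))
  )
  missing <- setdiff(unique(c(ed$source, ed$target)), nodes$node_id)
  if (length(missing))
    abort(paste0("Edge references node_id absent from node table: ",
                 paste(missing, collapse = ", ")))
  kg_graph(nodes, if (nrow(ed)) ed else NULL, directed = TRUE)
}

#' Read a seed disease cluster
#'
#' A seed cluster is a plain-text file with one node ID per line (the
#' analysis-driving set of related diseases, e.g. a cluster of 92
#' glioblastoma-related rare diseases).
#'
#' @param path Path to the plain-text ID list.
#' @return Character vector of node IDs.
#' @export
read_seed_cluster <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Write a seed disease cluster
#'
#' @param seeds Character vector of node IDs.
#' @inheritParams read_seed_cluster
#' @return `path`, invisibly.
#' @export
write_seed_cluster <- function(seeds, path) {
  writeLines(seeds, path)
  invisible(path)
}
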
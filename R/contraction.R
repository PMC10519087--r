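#' Find equivalence components to merge
#'
#' Restricts the graph to edges whose predicate is an equivalence predicate
#' (direction ignored) and returns the connected components of size >= 2:
#' each is a set of nodes that represent the same concept across source
#' resources and will be contracted into one merged node.
#'
#' @param graph A knowledge graph.
#' @param predicates Equivalence predicate names (default
#'   [kg_equivalence_predicates()]).
#' @return A `merge_plan`: list with `components` (list of character vectors
#'   of node IDs, each sorted) and `predicates`.
#' @export
find_equivalence_components <- function(graph,
                                        predicates = kg_equivalence_predicates()) {
  if (length(predicates) == 0) abort("`predicates` must be non-empty.")
  eidx <- which((igraph::edge_attr(graph, "predicate") %||% character(0))
                %in% predicates)
  comps <- list()
  if (length(eidx)) {
    sub <- igraph::subgraph_from_edges(graph, eidx, delete.vertices = TRUE)
    cc <- igraph::components(sub, mode = "weak")
    comps <- split(igraph::V(sub)$name, cc$membership)
    comps <- unname(lapply(comps[lengths(comps) >= 2], sort))
  }
  structure(list(components = comps, predicates = predicates),
            class = "merge_plan")
}

#' @method print merge_plan
#' @export
print.merge_plan <- function(x, ...) {
  cat("<merge_plan> ", length(x$components), " component(s), ",
      sum(lengths(x$components)), " node(s); predicates: ",
      paste(x$predicates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname profnet-tidiers
#' @export
tidy.merge_plan <- function(x, ...) {
  if (length(x$components) == 0)
    return(tibble(component = integer(0), node_id = character(0)))
  tibble(component = rep(seq_along(x$components), lengths(x$components)),
         node_id = unlist(x$components))
}

#' Filter synonymous labels from a merged node's label list
#'
#' After contraction the labels of merged members are concatenated; a label
#' that the synonym index records as a synonym of an earlier-retained label is
#' dropped (first-seen wins). E.g. when "Addison's Disease" and "Adrenal
#' aplasia" merge and the index lists the latter among the former's synonyms,
#' only "Addison's Disease" is retained.
#'
#' @param labels Character vector of candidate labels, in retention order.
#' @param synonym_index Named list mapping a label to its known synonyms
#'   (built from the members' `synonyms` fields).
#' @return Character vector of retained labels.
#' @export
filter_synonyms <- function(labels, synonym_index = list()) {
  retained <- character(0)
  known_syns <- character(0)
  for (lab in labels) {
    if (lab %in% retained) next
    if (lab %in% known_syns) next
    retained <- c(retained, lab)
    known_syns <- unique(c(known_syns, unlist(synonym_index[[lab]])))
  }
  retained
}

#' Contract equivalence components into merged nodes
#'
#' Optimizes a profile network by replacing each equivalence component with a
#' single merged node under three rules: (1) attributes of merged members are
#' concatenated, (2) edges between merged members are removed, and (3) edges
#' between an unmerged node and a member are reattached to the merged node.
#' Parallel post-contraction edges with the same predicate collapse to one;
#' with different predicates all are kept. Concatenated member labels are
#' synonym-filtered via the members' own `synonyms` fields (see
#' [filter_synonyms()]). The merged node's ID is the lexicographically
#' smallest member ID prefixed `"merged:"`; its category is the set of member
#' categories.
#'
#' @param graph A knowledge graph.
#' @param plan A `merge_plan` from [find_equivalence_components()], or `NULL`
#'   to compute one with `predicates`.
#' @inheritParams find_equivalence_components
#' @return The contracted knowledge graph. Member provenance is kept in the
#'   vertex attribute `member_ids`; retrieve it with [merge_report()].
#' @export
contract_kg <- function(graph, plan = NULL,
                        predicates = kg_equivalence_predicates()) {
  if (is.null(plan)) plan <- find_equivalence_components(graph, predicates)
  comps <- plan$components
  all_members <- unlist(comps)
  if (anyDuplicated(all_members))
    abort("Merge plan components overlap; plan invalid.")
  if (!all(all_members %in% igraph::V(graph)$name))
    abort("Merge plan references nodes absent from the graph.")
  if (length(comps) == 0) return(as_kg(graph))

  nd <- kg_nodes(graph)
  group_of <- stats::setNames(nd$node_id, nd$node_id)
  for (comp in comps) group_of[comp] <- paste0("merged:", min(comp))

  merged_rows <- map_dfr(comps, function(comp) {
    # member order = appearance order in the graph (first-seen wins for labels)
    m <- nd[nd$node_id %in% comp, ]
    syn_index <- stats::setNames(m$synonyms, m$primary_label)
    labels <- filter_synonyms(c(m$primary_label, unlist(m$alt_labels)),
                              syn_index)
    tibble(
      node_id = paste0("merged:", min(comp)),
      primary_label = labels[1],
      category = list(sort(unique(m$category))),
      source_resource = paste(sort(unique(unlist(
        .unpack(m$source_resource)))), collapse = .kg_sep),
      alt_labels = list(labels[-1]),
      synonyms = list(sort(unique(unlist(m$synonyms)))),
      external_codes = list(sort(unique(unlist(m$external_codes)))),
      member_ids = list(m$node_id)
    )
  })

  keep <- nd[!nd$node_id %in% all_members, ]
  keep$member_ids <- as.list(keep$node_id)
  # multi-category merged nodes keep the category set packed in one field
  merged_rows$category <- vapply(merged_rows$category, paste,
                                 character(1), collapse = .kg_sep)
  new_nodes <- bind_rows(keep, merged_rows)

  ed <- kg_edges(graph)
  ed$source <- unname(group_of[ed$source])
  ed$target <- unname(group_of[ed$target])
  ed <- ed[ed$source != ed$target, ] |>
    distinct(.data$source, .data$target, .data$predicate)

  out <- kg_graph(new_nodes, if (nrow(ed)) ed else NULL,
                  directed = igraph::is_directed(graph))
  igraph::vertex_attr(out, "member_ids") <- .pack(
    new_nodes$member_ids[match(igraph::V(out)$name, new_nodes$node_id)])
  as_kg(out)
}

#' Merge report of a contracted graph
#'
#' Lists every merged node with its member IDs, label and category set,
#' mirroring the merge audit a contraction run should leave behind (the
#' count of rows is the number of merged nodes). Note that reattachment
#' (rule 3) can create paths between concepts that were never directly
#' linked before contraction; this report is the place to audit such
#' inferred adjacencies.
#'
#' @param graph A contracted knowledge graph from [contract_kg()].
#' @return A tibble: `new_id`, `n_members`, `member_ids` (list-column),
#'   `primary_label`, `categories` (list-column).
#' @export
merge_report <- function(graph) {
  nd <- kg_nodes(graph)
  members <- .unpack(igraph::vertex_attr(graph, "member_ids") %||%
                       nd$node_id)
  keep <- lengths(members) >= 2
  tibble(
    new_id = nd$node_id[keep],
    n_members = lengths(members)[keep],
    member_ids = members[keep],
    primary_label = nd$primary_label[keep],
    categories = .unpack(nd$category[keep])
  )
}

#' Write a merge report as JSON
#'
#' @param graph A contracted knowledge graph.
#' @param path Output JSON path (map of `new_id` to member IDs).
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(graph, path) {
  rep <- merge_report(graph)
  jsonlite::write_json(stats::setNames(rep$member_ids, rep$new_id), path,
                       pretty = TRUE)
  invisible(path)
}
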
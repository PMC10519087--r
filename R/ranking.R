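#' Top-k nodes by one centrality measure
#'
#' @param table A `centrality_table` from [compute_centralities()].
#' @param measure One of `"degree"`, `"closeness"`, `"betweenness"`,
#'   `"eigenvector"`, `"pagerank"`.
#' @param k Number of nodes (default 5); ties break by `node_id` ascending,
#'   and fewer than `k` nodes returns them all.
#' @return Character vector of node IDs, highest score first.
#' @export
top_k_by_measure <- function(table, measure, k = 5) {
  measure <- match.arg(measure, .centrality_measures)
  if (nrow(table) == 0) abort("Centrality table is empty.")
  if (k < 1) abort("`k` must be >= 1.")
  table |>
    arrange(desc(.data[[measure]]), .data$node_id) |>
    slice_head(n = k) |>
    pull("node_id")
}

#' Min-max normalization to \[0, 1\]
#'
#' `x -> (x - min) / (max - min)`. When all values are equal the output is
#' all zeros (a conservative floor that keeps the aggregate score a lower
#' bound rather than crediting uninformative measures).
#'
#' @param x Numeric vector (non-empty).
#' @return Numeric vector in \[0, 1\], same order as `x`.
#' @examples
#' normalize_minmax(c(2, 4, 6))
#' @export
normalize_minmax <- function(x) {
  if (length(x) == 0) abort("`x` must be non-empty.")
  rng <- max(x) - min(x)
  if (rng == 0) return(rep(0, length(x)))
  (x - min(x)) / rng
}

#' Total Normalized Centrality Score (TNCS) table
#'
#' For each centrality measure the scores are min-max normalized to \[0, 1\]
#' and a node's TNCS is the sum of its five normalized scores, so TNCS ranges
#' from 0 to 5 and a node that is the argmax of all five raw measures scores
#' exactly 5. Two normalization scopes are supported:
#' \describe{
#'   \item{`top5_union`}{(default) each measure's top-`k` scores are
#'     normalized among themselves; nodes outside a measure's top-`k`
#'     contribute 0 for that measure, and only nodes in at least one top-`k`
#'     list appear in the table.}
#'   \item{`community_all`}{each measure is normalized over all nodes of the
#'     community.}
#' }
#'
#' @inheritParams top_k_by_measure
#' @param scope Normalization scope (see Details).
#' @param k Top-list size per measure under `top5_union` (default 5).
#' @return A `tncs_table` tibble: `node_id`, the five normalized measures,
#'   and `tncs`, sorted by `tncs` descending (ties by `node_id`).
#' @export
tncs_table <- function(table, scope = c("top5_union", "community_all"),
                       k = 5) {
  scope <- match.arg(scope)
  if (nrow(table) == 0) abort("Centrality table is empty.")
  norm_one <- function(measure) {
    if (scope == "top5_union") {
      ids <- top_k_by_measure(table, measure, k)
      vals <- table[[measure]][match(ids, table$node_id)]
    } else {
      ids <- table$node_id
      vals <- table[[measure]]
    }
    tibble(node_id = ids, measure = measure,
           normalized = normalize_minmax(vals))
  }
  long <- map_dfr(.centrality_measures, norm_one)
  out <- long |>
    tidyr::pivot_wider(names_from = "measure", values_from = "normalized",
                       values_fill = 0) |>
    mutate(tncs = .data$degree + .data$closeness + .data$betweenness +
             .data$eigenvector + .data$pagerank) |>
    arrange(desc(.data$tncs), .data$node_id)
  attr(out, "scope") <- scope
  attr(out, "k") <- k
  class(out) <- c("tncs_table", class(out))
  out
}

#' Rank drug repurposing/repositioning candidates
#'
#' Runs the full within-community influence analysis: communities are ranked
#' by modularity score ([rank_communities()]), the five centralities are
#' computed inside each retained community, scores are min-max normalized and
#' summed into the TNCS, and each community's highest-TNCS node (ties
#' included) is flagged as that community's candidate. Labels and categories
#' are carried so merged disease/gene/drug bundles stay legible.
#'
#' @inheritParams community_score
#' @param min_size Minimum community size analyzed (default 4).
#' @param config A [centrality_config()].
#' @param scope,k TNCS normalization scope and top-list size, see
#'   [tncs_table()].
#' @return A `candidate_report`: list with `communities` (ranked score
#'   tibble), `records` (per-node TNCS tibble with `community` column),
#'   `candidates` (one block per community, sorted by community score),
#'   `top_lists` (per community and measure the top-`k` node IDs), `scope`,
#'   `k`.
#' @export
rank_candidates <- function(graph, partition, min_size = 4,
                            resolution = partition$resolution,
                            config = centrality_config(),
                            scope = c("top5_union", "community_all"), k = 5) {
  scope <- match.arg(scope)
  ranked <- rank_communities(graph, partition, min_size, resolution)
  if (nrow(ranked) == 0)
    abort("No community passes the minimum-size filter.")
  nd <- kg_nodes(graph)
  describe <- function(ids) {
    i <- match(ids, nd$node_id)
    vapply(i, function(j) {
      labs <- unique(c(nd$primary_label[j], nd$alt_labels[[j]]))
      paste(labs, collapse = " + ")
    }, character(1))
  }
  per_comm <- map(ranked$community, function(cm) {
    sub <- community_subgraph(graph, partition, cm)
    cent <- compute_centralities(sub, config)
    tt <- tncs_table(cent, scope = scope, k = k)
    tops <- map_dfr(.centrality_measures, function(ms)
      tibble(community = cm, measure = ms,
             rank = seq_len(min(k, nrow(cent))),
             node_id = top_k_by_measure(cent, ms, k)))
    list(tncs = mutate(tibble::as_tibble(tt), community = cm,
                       .before = 1),
         tops = tops)
  })
  records <- map_dfr(per_comm, "tncs")
  top_lists <- map_dfr(per_comm, "tops")
  candidates <- records |>
    group_by(.data$community) |>
    filter(.data$tncs == max(.data$tncs)) |>
    ungroup() |>
    mutate(description = describe(.data$node_id),
           category = vapply(.unpack(nd$category[match(.data$node_id,
                                                       nd$node_id)]),
                             paste, character(1), collapse = ", ")) |>
    left_join(select(ranked, "community", community_score = "score"),
              by = "community") |>
    arrange(desc(.data$community_score), desc(.data$tncs), .data$node_id) |>
    select("community", "community_score", "node_id", "description",
           "category", "tncs")
  structure(list(communities = ranked, records = records,
                 candidates = candidates, top_lists = top_lists,
                 scope = scope, k = k),
            class = "candidate_report")
}

#' @method print candidate_report
#' @export
print.candidate_report <- function(x, ...) {
  cat("<candidate_report> ", nrow(x$communities),
      " ranked communities; normalization scope: ", x$scope,
      " (k = ", x$k, ")\n", sep = "")
  print(x$candidates)
  invisible(x)
}

#' @rdname profnet-tidiers
#' @export
tidy.candidate_report <- function(x, ...) {
  cand <- paste(x$candidates$community, x$candidates$node_id)
  x$records |>
    mutate(is_candidate = paste(.data$community, .data$node_id) %in% cand)
}

#' @rdname profnet-tidiers
#' @export
glance.candidate_report <- function(x, ...) {
  tibble(n_communities = nrow(x$communities),
         n_candidates = nrow(x$candidates),
         max_tncs = max(x$records$tncs), scope = x$scope, k = x$k)
}

#' Write a candidate report
#'
#' Writes the report as JSON and, optionally, as a Markdown table
#' (community index, candidate description, TNCS).
#'
#' @param report A `candidate_report`.
#' @param path JSON output path.
#' @param md_path Optional Markdown output path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path, md_path = NULL) {
  jsonlite::write_json(
    list(scope = report$scope, k = report$k,
         communities = report$communities,
         candidates = report$candidates,
         records = report$records,
         top_lists = report$top_lists),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(md_path)) {
    rows <- report$candidates
    lines <- c("| Community | Candidate | Category | TNCS |",
               "|---|---|---|---|",
               sprintf("| %d | %s | %s | %.3f |", rows$community,
                       rows$description, rows$category, rows$tncs))
    writeLines(lines, md_path)
  }
  invisible(path)
}
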
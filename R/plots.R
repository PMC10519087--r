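#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point facet_wrap
#'   labs theme_minimal
NULL

#' Plot a TNCS table
#'
#' Bar chart of per-node TNCS, stacked by the five normalized centrality
#' contributions.
#'
#' @param object A `tncs_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tncs_table <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(cols = all_of(.centrality_measures),
                        names_to = "measure", values_to = "normalized")
  ggplot(long, aes(x = stats::reorder(.data$node_id, .data$tncs),
                   y = .data$normalized, fill = .data$measure)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Total normalized centrality score (TNCS)",
         fill = "Measure") +
    theme_minimal()
}

#' Plot a candidate report
#'
#' One point per ranked community: its modularity score against its
#' candidate's TNCS, labelled with the candidate description.
#'
#' @param object A `candidate_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candidate_report <- function(object, ...) {
  ggplot(object$candidates,
         aes(x = .data$community_score, y = .data$tncs)) +
    geom_point(size = 2) +
    ggplot2::geom_text(aes(label = .data$description),
                       vjust = -0.8, size = 2.8, check_overlap = TRUE) +
    ggplot2::ylim(0, 5.3) +
    labs(x = "Community modularity score", y = "Candidate TNCS") +
    theme_minimal()
}

#' Plot a partition
#'
#' Community size distribution, highlighting the classes large enough
#' (> 3 nodes) for within-class centrality analysis.
#'
#' @param object A `kg_partition`.
#' @param min_size Size threshold used for the highlight (default 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kg_partition <- function(object, min_size = 4, ...) {
  sizes <- tidy(object) |>
    count(.data$community, name = "n_nodes") |>
    mutate(analyzed = .data$n_nodes >= min_size)
  ggplot(sizes, aes(x = stats::reorder(factor(.data$community), -.data$n_nodes),
                    y = .data$n_nodes, fill = .data$analyzed)) +
    geom_col() +
    labs(x = "Modularity class", y = "Nodes", fill = "Analyzed") +
    theme_minimal()
}
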
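#' Configuration for the synthetic knowledge-graph generator
#'
#' The generator emulates the structure of a multi-resource biomedical
#' knowledge graph at desk scale: the same concept can appear under several
#' source resources joined by equivalence edges, domain edges
#' (disease-gene, disease-drug, gene-drug, disease-phenotype) follow a
#' planted-partition model with known communities, and each community carries
#' one planted hub node connected to every other member. Defaults give a
#' 200-concept graph with four well-separated communities (`p_in = 0.3`,
#' `p_out = 0.01`), three resources with a 15% cross-resource duplication
#' rate, and a 10-disease seed cluster.
#'
#' @param n_diseases,n_genes,n_drugs,n_phenotypes Concept counts per category.
#' @param n_resources Number of source resources (>= 1).
#' @param duplication_prob Probability that a concept is re-emitted under an
#'   extra resource and linked to its original by one equivalence edge.
#' @param n_communities Number of planted communities.
#' @param p_in,p_out Intra-/inter-community edge probabilities (`p_in > p_out`).
#' @param n_seed_diseases Size of the generated seed disease cluster.
#' @param seed Integer RNG seed; the generator draws from a single stream
#'   seeded per call and restores the caller's RNG state.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_diseases = 80, n_genes = 70, n_drugs = 30,
                         n_phenotypes = 20, n_resources = 3,
                         duplication_prob = 0.15, n_communities = 4,
                         p_in = 0.3, p_out = 0.01, n_seed_diseases = 10,
                         seed = 42L) {
  cfg <- list(n_diseases = n_diseases, n_genes = n_genes, n_drugs = n_drugs,
              n_phenotypes = n_phenotypes, n_resources = n_resources,
              duplication_prob = duplication_prob,
              n_communities = n_communities, p_in = p_in, p_out = p_out,
              n_seed_diseases = n_seed_diseases, seed = as.integer(seed))
  .validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

.validate_synth_config <- function(cfg) {
  bad <- character(0)
  counts <- c("n_diseases", "n_genes", "n_drugs", "n_phenotypes",
              "n_resources", "n_communities", "n_seed_diseases")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]])) bad <- c(bad, f)
  for (f in c("duplication_prob", "p_in", "p_out"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) bad <- c(bad, f)
  if (is.numeric(cfg$p_in) && is.numeric(cfg$p_out) && cfg$p_in <= cfg$p_out)
    bad <- c(bad, "p_in/p_out (require p_in > p_out)")
  if (is.numeric(cfg$n_seed_diseases) && is.numeric(cfg$n_diseases) &&
      cfg$n_seed_diseases > cfg$n_diseases)
    bad <- c(bad, "n_seed_diseases (exceeds n_diseases)")
  if (length(bad))
    abort(paste0("Invalid synthetic KG configuration field(s): ",
                 paste(bad, collapse = ", ")))
  invisible(cfg)
}

.domain_predicate <- function(cat_a, cat_b) {
  key <- paste(sort(c(cat_a, cat_b)), collapse = "-")
  switch(key,
    "disease-gene" = "associated_with",
    "disease-drug" = "has_treatment",
    "drug-gene" = "targets",
    "disease-phenotype" = "has_phenotype",
    "related_to")
}

#' Generate a synthetic multi-resource knowledge graph
#'
#' Produces a knowledge graph together with the ground truth needed to
#' validate every downstream stage: the planted equivalence components, the
#' planted community of every node, and the planted hub of each community.
#' Concepts are assigned categories and communities; domain edges are drawn
#' independently with probability `p_in` inside a community and `p_out`
#' across communities; one hub per community is wired to all of its
#' community's members; each concept is duplicated under an extra resource
#' with probability `duplication_prob`, the duplicate linked to its original
#' by a uniformly sampled equivalence predicate. A duplicate's primary label
#' is one of the original's synonyms (so label synonym filtering has work to
#' do after contraction) and it carries one spurious alternative label.
#'
#' @param config A [synth_config()].
#' @return A list with elements `graph` (a knowledge graph) and `truth`, the
#'   ground truth list: `equivalence_components` (list of node-ID sets),
#'   `community_of` (named integer vector, 1-based planted community per
#'   node, duplicates inheriting their original's community), `hubs`
#'   (named by community).
#' @examples
#' sim <- generate_kg(synth_config(n_diseases = 20, n_genes = 15,
#'                                 n_drugs = 5, n_phenotypes = 5,
#'                                 n_communities = 2, seed = 1))
#' igraph::vcount(sim$graph)
#' @export
generate_kg <- function(config = synth_config()) {
  .validate_synth_config(config)
  withr::local_seed(config$seed)

  cats <- c(rep("disease", config$n_diseases), rep("gene", config$n_genes),
            rep("drug", config$n_drugs), rep("phenotype", config$n_phenotypes))
  n <- length(cats)
  prefix <- c(disease = "DIS", gene = "GENE", drug = "DRUG", phenotype = "PHE")
  node_id <- paste0(prefix[cats], ":",
                    formatC(stats::ave(seq_len(n), cats, FUN = seq_along),
                            width = 4, flag = "0"))
  label <- paste(c(disease = "Disease", gene = "Gene", drug = "Drug",
                   phenotype = "Phenotype")[cats],
                 sub("^[A-Z]+:", "", node_id))
  resources <- paste0("RES", seq_len(config$n_resources))
  src <- sample(resources, n, replace = TRUE)
  synonyms <- lapply(label, function(l) paste0(l, " (", c("alias", "variant"),
                                               ")"))
  # balanced community assignment over a shuffled node order
  community <- sample(rep_len(seq_len(config$n_communities), n))

  nodes <- tibble(node_id = node_id, primary_label = label, category = cats,
                  source_resource = src, synonyms = synonyms)

  # planted-partition domain edges over unordered pairs
  pr <- utils::combn(n, 2)
  same <- community[pr[1, ]] == community[pr[2, ]]
  p <- ifelse(same, config$p_in, config$p_out)
  keep <- stats::runif(ncol(pr)) < p
  a <- pr[1, keep]; b <- pr[2, keep]
  flip <- stats::runif(length(a)) < 0.5
  s <- ifelse(flip, b, a); t <- ifelse(flip, a, b)
  edges <- tibble(source = node_id[s], target = node_id[t],
                  predicate = mapply(.domain_predicate, cats[s], cats[t]))

  # one planted hub per community, wired to every other member
  hubs <- vapply(seq_len(config$n_communities),
                 function(k) node_id[which(community == k)[1]], character(1))
  hub_edges <- map_dfr(seq_len(config$n_communities), function(k) {
    members <- setdiff(node_id[community == k], hubs[k])
    tibble(source = hubs[k], target = members,
           predicate = mapply(.domain_predicate,
                              cats[match(hubs[k], node_id)],
                              cats[match(members, node_id)]))
  })
  edges <- bind_rows(edges, hub_edges) |>
    distinct(.data$source, .data$target, .data$predicate)
  # hub wiring may duplicate a planted edge in the opposite direction;
  # keep one adjacency per pair per predicate
  pair_key <- paste(pmin(edges$source, edges$target),
                    pmax(edges$source, edges$target), edges$predicate)
  edges <- edges[!duplicated(pair_key), ]

  # cross-resource duplicates joined by equivalence edges
  dup_idx <- which(stats::runif(n) < config$duplication_prob)
  equivalence_components <- list()
  if (length(dup_idx)) {
    dup_id <- paste0(node_id[dup_idx], "@dup")
    dup_nodes <- tibble(
      node_id = dup_id,
      primary_label = vapply(dup_idx, function(i) synonyms[[i]][1], character(1)),
      category = cats[dup_idx],
      source_resource = vapply(src[dup_idx], function(r) {
        pool <- setdiff(resources, r)
        if (length(pool)) sample(pool, 1) else r
      }, character(1)),
      synonyms = synonyms[dup_idx],
      alt_labels = lapply(label[dup_idx], function(l) paste0(l, " [dup form]"))
    )
    eq_edges <- tibble(
      source = node_id[dup_idx], target = dup_id,
      predicate = sample(kg_equivalence_predicates(), length(dup_idx),
                         replace = TRUE))
    flip <- stats::runif(length(dup_idx)) < 0.5
    tmp <- eq_edges$source[flip]
    eq_edges$source[flip] <- eq_edges$target[flip]
    eq_edges$target[flip] <- tmp
    nodes <- bind_rows(nodes, dup_nodes)
    edges <- bind_rows(edges, eq_edges)
    equivalence_components <- lapply(seq_along(dup_idx), function(i)
      c(node_id[dup_idx[i]], dup_id[i]))
    community <- c(community, community[dup_idx])
    node_id_all <- c(node_id, dup_id)
  } else {
    node_id_all <- node_id
  }

  graph <- kg_graph(nodes, edges, directed = TRUE)
  truth <- list(
    equivalence_components = equivalence_components,
    community_of = stats::setNames(as.integer(community), node_id_all),
    hubs = stats::setNames(hubs, seq_len(config$n_communities))
  )
  list(graph = graph, truth = truth)
}

#' Generate a seed disease cluster from a synthetic graph
#'
#' Draws `n_seed_diseases` disease IDs, preferentially from one planted
#' community (the community of the first planted hub), mimicking a cluster of
#' related diseases used to seed profile-network extraction.
#'
#' @param config A [synth_config()].
#' @param truth The ground truth returned by [generate_kg()].
#' @return Character vector of disease node IDs.
#' @export
generate_seed_cluster <- function(config, truth) {
  .validate_synth_config(config)
  withr::local_seed(config$seed + 1L)
  ids <- names(truth$community_of)
  base <- ids[!grepl("@dup$", ids)]
  diseases <- base[startsWith(base, "DIS:")]
  if (config$n_seed_diseases > length(diseases))
    abort(paste0("n_seed_diseases (", config$n_seed_diseases,
                 ") exceeds available diseases (", length(diseases), ")."))
  focal <- truth$community_of[[truth$hubs[[1]]]]
  in_focal <- diseases[truth$community_of[diseases] == focal]
  other <- setdiff(diseases, in_focal)
  pool <- c(sample(in_focal), sample(other))
  pool[seq_len(config$n_seed_diseases)]
}
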
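hits_matrix <- function(proteins) {
  hit_cols <- grep("^hits_rep", names(proteins), value = TRUE)
  if (!length(hit_cols)) abort("protein table needs hits_rep1..hits_repK columns")
  as.matrix(proteins[hit_cols])
}

#' Filter proteins by replicated spectral support
#'
#' A protein is retained when the number of replicate crosslinking
#' experiments with at least `min_hits` spectral hits is at least
#' `min_replicates` (defaults: >= 10 hits in >= 2 of the replicates).
#' Idempotent.
#'
#' @param proteins Tibble with `protein_id`, `length_aa` and replicate hit
#'   columns `hits_rep1`, `hits_rep2`, ...
#' @param min_hits Minimum spectral hits within a replicate.
#' @param min_replicates Minimum number of qualifying replicates.
#' @return The retained rows of `proteins`.
#' @export
#' @examples
#' p <- tibble::tibble(protein_id = "A", length_aa = 300,
#'                     hits_rep1 = 12, hits_rep2 = 11, hits_rep3 = 0)
#' nrow(filter_proteins(p))  # 1
filter_proteins <- function(proteins, min_hits = 10, min_replicates = 2) {
  stopifnot(min_hits >= 1, min_replicates >= 1)
  proteins <- as_tibble(proteins)
  hits <- hits_matrix(proteins)
  keep <- rowSums(hits >= min_hits) >= min_replicates
  proteins[keep, , drop = FALSE]
}

#' Build a filtered contact graph
#'
#' Applies [filter_proteins()] and drops edges touching removed proteins
#' (and self-loops, which are invalid contacts).
#'
#' @inheritParams filter_proteins
#' @param edges Tibble with `protein_a`, `protein_b` and optionally
#'   `crosslink_count`.
#' @return A list of class `contact_graph` with elements `proteins`,
#'   `edges` and the igraph object `graph`.
#' @export
build_contactome <- function(proteins, edges, min_hits = 10, min_replicates = 2) {
  kept <- filter_proteins(proteins, min_hits, min_replicates)
  edges <- as_tibble(edges)
  edges <- edges[edges$protein_a %in% kept$protein_id &
                   edges$protein_b %in% kept$protein_id &
                   edges$protein_a != edges$protein_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = kept$protein_id)
  )
  structure(list(proteins = kept, edges = edges, graph = g),
            class = "contact_graph")
}

#' Length-normalized degree
#'
#' Degree divided by protein length in amino acids (most abundant
#' isoform), compensating for the greater interaction potential of very
#' large proteins such as titin.
#'
#' @param degree Edge counts.
#' @param length_aa Protein lengths (aa), > 0.
#' @return Per-residue degree.
#' @export
#' @examples
#' normalized_degree(500, 250)  # 2
normalized_degree <- function(degree, length_aa) {
  if (any(length_aa <= 0)) abort("length_aa must be positive")
  degree / length_aa
}

#' Classify central hubs, hub connectors and clusters
#'
#' Central hubs are nodes with degree > 4 on the filtered graph. A hub
#' connector is a node of degree <= 4 whose removal places at least two
#' central hubs that were connected through it into different components
#' (an articulation-style test restricted to hub pairs). Clusters are
#' connected components, indexed deterministically in order of each
#' component's lexicographically smallest protein id.
#'
#' @param x A `contact_graph` from [build_contactome()], or a tibble of
#'   edges (`protein_a`, `protein_b`).
#' @param proteins Optional protein tibble (used for `length_aa`
#'   normalization and to include isolated nodes) when `x` is an edge
#'   table.
#' @return Tibble: `protein_id`, `degree`, `normalized_degree`, `role`
#'   (central_hub / hub_connector / other), `cluster_id`.
#' @export
classify_hubs <- function(x, proteins = NULL) {
  if (inherits(x, "contact_graph")) {
    g <- x$graph
    proteins <- x$proteins
  } else {
    edges <- as_tibble(x)
    verts <- if (!is.null(proteins)) {
      data.frame(name = proteins$protein_id)
    } else {
      data.frame(name = sort(unique(c(edges$protein_a, edges$protein_b))))
    }
    g <- igraph::graph_from_data_frame(
      edges[, c("protein_a", "protein_b"), drop = FALSE],
      directed = FALSE, vertices = verts)
  }
  if (igraph::vcount(g) == 0) {
    return(tibble(protein_id = character(), degree = integer(),
                  normalized_degree = numeric(), role = character(),
                  cluster_id = integer()))
  }
  ids <- igraph::V(g)$name
  deg <- unname(igraph::degree(g))
  comp <- igraph::components(g)
  # deterministic cluster ids: order components by their smallest member id
  first_member <- vapply(seq_len(comp$no), function(i) {
    min(ids[comp$membership == i])
  }, "")
  cluster_id <- rank(first_member)[comp$membership]
  hubs <- ids[deg > 4]
  is_connector <- vapply(seq_along(ids), function(i) {
    if (deg[i] > 4 || deg[i] == 0) return(FALSE)
    local_hubs <- hubs[hubs != ids[i] &
                         cluster_id[match(hubs, ids)] == cluster_id[i]]
    if (length(local_hubs) < 2) return(FALSE)
    g2 <- igraph::delete_vertices(g, ids[i])
    comp2 <- igraph::components(g2)$membership[local_hubs]
    length(unique(comp2)) > 1
  }, TRUE)
  role <- ifelse(deg > 4, "central_hub",
                 ifelse(is_connector, "hub_connector", "other"))
  out <- tibble(protein_id = ids, degree = as.integer(deg),
                normalized_degree = NA_real_, role = role,
                cluster_id = as.integer(cluster_id))
  if (!is.null(proteins) && "length_aa" %in% names(proteins)) {
    len <- proteins$length_aa[match(out$protein_id, proteins$protein_id)]
    out$normalized_degree <- normalized_degree(out$degree, len)
  }
  arrange(out, .data$cluster_id, dplyr::desc(.data$degree), .data$protein_id)
}

#' Tally clusters, central hubs and connectors
#'
#' @param labels Output of [classify_hubs()].
#' @return One-row tibble: `n_clusters`, `n_central_hubs`,
#'   `n_connectors`, `n_other`.
#' @export
count_roles <- function(labels) {
  tibble(
    n_clusters = length(unique(labels$cluster_id)),
    n_central_hubs = sum(labels$role == "central_hub"),
    n_connectors = sum(labels$role == "hub_connector"),
    n_other = sum(labels$role == "other")
  )
}

#' Annotation enrichment of a selected protein set
#'
#' Upper-tail hypergeometric test for observing at least the seen number
#' of tagged proteins when drawing `|selected|` proteins from the
#' background universe.
#'
#' @param selected Character vector of selected protein ids (a subset of
#'   the background).
#' @param annotation_tag The tag tested for enrichment.
#' @param background Tibble with `protein_id` and a `tags` column
#'   (character; multiple tags separated by `;` or `,`).
#' @return One-row tibble: `tag`, `count`, `n_selected`, `n_tagged`,
#'   `n_background`, `p`.
#' @export
annotation_enrichment <- function(selected, annotation_tag, background) {
  background <- as_tibble(background)
  if (nrow(background) == 0) abort("empty background universe")
  if (!all(selected %in% background$protein_id)) {
    abort("selected proteins must be a subset of the background")
  }
  has_tag <- vapply(strsplit(background$tags %||% "", "[;,]\\s*"),
                    function(x) annotation_tag %in% x, TRUE)
  K <- sum(has_tag)
  N <- nrow(background)
  n <- length(selected)
  k <- sum(selected %in% background$protein_id[has_tag])
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(tag = annotation_tag, count = k, n_selected = n,
         n_tagged = K, n_background = N, p = p)
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("contact_graph: %d proteins, %d crosslink edges\n",
              nrow(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Plot a contact graph colored by role
#'
#' @param x A `contact_graph`.
#' @param labels Optional precomputed [classify_hubs()] output.
#' @param seed Layout seed.
#' @return A ggplot of the network (Fruchterman-Reingold layout).
#' @export
plot_contactome <- function(x, labels = NULL, seed = 1L) {
  labels <- labels %||% classify_hubs(x)
  lay <- local_seed(seed, igraph::layout_with_fr(x$graph))
  ids <- igraph::V(x$graph)$name
  nodes <- tibble(protein_id = ids, x = lay[, 1], y = lay[, 2]) %>%
    left_join(labels, by = "protein_id")
  ed <- x$edges %>%
    left_join(select(nodes, "protein_id", xa = "x", ya = "y"),
              by = c(protein_a = "protein_id")) %>%
    left_join(select(nodes, "protein_id", xb = "x", yb = "y"),
              by = c(protein_b = "protein_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$role,
                                     size = .data$degree)) +
    ggplot2::scale_colour_manual(values = c(central_hub = "red",
                                            hub_connector = "darkgreen",
                                            other = "grey40")) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Aggregate contactome",
                  colour = "role", size = "degree")
}
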
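as_igraph <- function(network) {
  if (inherits(network, "cor_network")) network$graph
  else if (igraph::is_igraph(network)) network
  else stop_dcornet("expected a cor_network or igraph object")
}

#' Global, per-node and per-edge topology of a correlation network
#'
#' The metric suite commonly reported for unweighted co-expression networks
#' (as by Cytoscape's NetworkAnalyzer): density, average clustering
#' coefficient, Freeman degree centralization, degree heterogeneity,
#' diameter, radius, average shortest path length, degree statistics, plus
#' per-node degree/clustering/betweenness/eccentricity and a ranked
#' edge-betweenness table.
#'
#' Conventions: the clustering coefficient of a node with degree < 2 is 0 and
#' is included in the average (set `include_low_degree = FALSE` to average
#' over degree >= 2 nodes only); centralization is
#' `(n/(n-2)) * (max_deg/(n-1) - density)` and is `NA` for n < 3;
#' heterogeneity is `sqrt(population variance of degree) / mean degree`;
#' betweenness is unnormalized shortest-path (Brandes) betweenness with each
#' unordered pair counted once and endpoints excluded. On a fragmented graph
#' the distance-based metrics (diameter, radius, eccentricity, average
#' shortest path length) are computed on the largest connected component and
#' the report is flagged `fragmented`; `avg_shortest_path_components` gives
#' the unweighted mean over all components with >= 2 nodes.
#'
#' @param network A `cor_network` or igraph graph (>= 2 nodes).
#' @param include_low_degree Include degree-<2 nodes (as 0) in the average
#'   clustering coefficient (default `TRUE`).
#' @return A `topology_report`: list with `global` (named list of metrics),
#'   `nodes` (data.frame), `edges` (ranked data.frame), `fragmented`.
#' @export
topology_report <- function(network, include_low_degree = TRUE) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n < 2) stop_dcornet("topology requires at least 2 nodes")
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  density <- 2 * m / (n * (n - 1))

  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc_local) <- igraph::V(g)$name
  avg_cc <- if (include_low_degree) mean(cc_local) else {
    elig <- deg >= 2
    if (any(elig)) mean(cc_local[elig]) else NA_real_
  }
  centralization <- if (n >= 3) (n / (n - 2)) * (max(deg) / (n - 1) - density) else NA_real_
  mean_deg <- mean(deg)
  heterogeneity <- if (mean_deg > 0) sqrt(mean((deg - mean_deg)^2)) / mean_deg else NA_real_

  comp <- igraph::components(g)
  fragmented <- comp$no > 1
  lcc_ids <- which(comp$membership == which.max(comp$csize))
  lcc <- igraph::induced_subgraph(g, lcc_ids)
  ecc_lcc <- igraph::eccentricity(lcc)
  diameter <- if (igraph::vcount(lcc) > 1) max(ecc_lcc) else 0
  radius <- if (igraph::vcount(lcc) > 1) min(ecc_lcc) else 0
  aspl_lcc <- if (igraph::vcount(lcc) > 1) igraph::mean_distance(lcc) else NA_real_
  comp_aspl <- vapply(seq_len(comp$no), function(k) {
    ids <- which(comp$membership == k)
    if (length(ids) < 2) return(NA_real_)
    igraph::mean_distance(igraph::induced_subgraph(g, ids))
  }, numeric(1))
  aspl_components <- if (all(is.na(comp_aspl))) NA_real_ else mean(comp_aspl, na.rm = TRUE)

  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  ecc_all <- igraph::eccentricity(g)  # within each node's own component
  nodes <- data.frame(gene = igraph::V(g)$name, degree = as.integer(deg),
                      clustering_coefficient = as.numeric(cc_local),
                      betweenness = as.numeric(btw),
                      eccentricity = as.numeric(ecc_all),
                      stringsAsFactors = FALSE, row.names = NULL)

  edges <- edge_betweenness_ranking(g)

  global <- list(
    n_nodes = n, n_edges = m, density = density,
    avg_clustering_coefficient = avg_cc,
    centralization = centralization, heterogeneity = heterogeneity,
    diameter = as.numeric(diameter), radius = as.numeric(radius),
    avg_shortest_path_length = aspl_lcc,
    avg_shortest_path_components = aspl_components,
    degree_min = min(deg), degree_max = max(deg),
    degree_mean = mean_deg, degree_median = stats::median(deg))
  structure(list(global = global, nodes = nodes, edges = edges,
                 fragmented = fragmented),
            class = "topology_report")
}

#' @rdname topology_report
#' @export
global_metrics <- function(network, include_low_degree = TRUE) {
  topology_report(network, include_low_degree = include_low_degree)$global
}

#' @export
print.topology_report <- function(x, ...) {
  g <- x$global
  cat("Network topology:", g$n_nodes, "nodes,", g$n_edges, "edges",
      if (x$fragmented) "(fragmented; distances on largest component)" else "", "\n")
  cat(sprintf("  density %.3f | avg clustering %.3f | centralization %s | heterogeneity %.3f\n",
              g$density, g$avg_clustering_coefficient,
              ifelse(is.na(g$centralization), "NA", sprintf("%.3f", g$centralization)),
              g$heterogeneity))
  cat(sprintf("  diameter %g | radius %g | avg path length %.3f\n",
              g$diameter, g$radius, g$avg_shortest_path_length))
  cat(sprintf("  degree min/median/mean/max: %g / %g / %.2f / %g\n",
              g$degree_min, g$degree_median, g$degree_mean, g$degree_max))
  invisible(x)
}

#' Unnormalized shortest-path node betweenness
#'
#' Brandes betweenness on the undirected graph: for each unordered pair of
#' distinct nodes, the fraction of shortest paths passing through an
#' intermediate node, summed over pairs (endpoints excluded, no
#' normalization).
#'
#' @param network A `cor_network` or igraph graph.
#' @return Named numeric vector, one value per node.
#' @export
node_betweenness <- function(network) {
  g <- as_igraph(network)
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' Ranked edge-betweenness table
#'
#' Edge betweenness (number of shortest paths over unordered node pairs
#' traversing the edge, fractional under ties), ranked descending; rank 1 is
#' the highest-betweenness edge and ties share the minimum rank.
#'
#' @param network A `cor_network` or igraph graph with >= 0 edges.
#' @return data.frame with `gene_a`, `gene_b`, `betweenness`, `rank`,
#'   sorted by decreasing betweenness.
#' @export
edge_betweenness_ranking <- function(network) {
  g <- as_igraph(network)
  if (igraph::ecount(g) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      betweenness = numeric(0), rank = integer(0)))
  }
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  out <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                    betweenness = as.numeric(eb),
                    rank = rank_desc_min(eb), stringsAsFactors = FALSE)
  out[order(-out$betweenness, out$gene_a, out$gene_b), , drop = FALSE]
}
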
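# sorted unordered-pair keys for an igraph edge list
graph_edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g, names = TRUE)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
}

#' Merge two condition networks and score node rewiring
#'
#' Builds the union graph of the condition-A and condition-B networks,
#' labels each edge `both`, `A_only` or `B_only`, and scores each node's
#' rewiring DyNet-style: with `b` incident A-only and `c` incident B-only
#' edges, `dn = sqrt(b + c)` (the square root of the symmetric-difference
#' count of the node's incident edge sets in the two states), and
#' `dn_corrected = dn / max(1, (degree_A + degree_B) / 2)`. Nodes present in
#' only one condition get degree 0 and betweenness 0 in the other, so genes
#' that lose all their edges in one condition rank among the most rewired.
#'
#' @param net_A,net_B `cor_network` objects (conventionally A = BRAF wt,
#'   B = BRAF V600E).
#' @return A `merged_network`: list with `graph` (igraph union graph, edge
#'   attribute `class`), `nodes` (per-node data.frame: degrees, dn scores,
#'   betweenness in each condition and `betweenness_delta`), `edge_counts`
#'   (named counts: both, A_only, B_only), `names_AB`.
#' @export
merge_networks <- function(net_A, net_B) {
  gA <- as_igraph(net_A); gB <- as_igraph(net_B)
  keysA <- graph_edge_keys(gA); keysB <- graph_edge_keys(gB)
  all_keys <- sort(union(keysA, keysB))
  cls <- ifelse(all_keys %in% keysA & all_keys %in% keysB, "both",
                ifelse(all_keys %in% keysA, "A_only", "B_only"))
  nodes <- sort(union(igraph::V(gA)$name, igraph::V(gB)$name))
  if (length(all_keys) > 0) {
    parts <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
    edges <- data.frame(from = parts[, 1], to = parts[, 2], class = cls,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        class = character(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))

  count_incident <- function(parts, cls, want) {
    tab <- table(factor(c(parts[cls == want, 1], parts[cls == want, 2]),
                        levels = nodes))
    as.numeric(tab)
  }
  if (length(all_keys) > 0) {
    a_cnt <- count_incident(parts, cls, "both")
    b_cnt <- count_incident(parts, cls, "A_only")
    c_cnt <- count_incident(parts, cls, "B_only")
  } else {
    a_cnt <- b_cnt <- c_cnt <- numeric(length(nodes))
  }
  degree_A <- a_cnt + b_cnt
  degree_B <- a_cnt + c_cnt
  dn <- sqrt(b_cnt + c_cnt)
  dn_corrected <- dn / pmax(1, (degree_A + degree_B) / 2)

  btwA <- stats::setNames(rep(0, length(nodes)), nodes)
  btwB <- btwA
  bA <- igraph::betweenness(gA, directed = FALSE, normalized = FALSE)
  bB <- igraph::betweenness(gB, directed = FALSE, normalized = FALSE)
  btwA[names(bA)] <- bA
  btwB[names(bB)] <- bB

  node_df <- data.frame(
    gene = nodes,
    degree_A = as.integer(degree_A), degree_B = as.integer(degree_B),
    rewiring_dn = dn, rewiring_dn_corrected = dn_corrected,
    betweenness_A = as.numeric(btwA), betweenness_B = as.numeric(btwB),
    betweenness_delta = abs(as.numeric(btwA) - as.numeric(btwB)),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(graph = g, nodes = node_df,
                 edge_counts = c(both = sum(cls == "both"),
                                 A_only = sum(cls == "A_only"),
                                 B_only = sum(cls == "B_only"))),
            class = "merged_network")
}

#' @export
print.merged_network <- function(x, ...) {
  ec <- x$edge_counts
  cat("Merged two-state network:", nrow(x$nodes), "nodes;",
      sum(ec), "edges (", ec[["both"]], "shared,", ec[["A_only"]],
      "A-only,", ec[["B_only"]], "B-only )\n")
  top <- utils::head(x$nodes[order(-x$nodes$rewiring_dn), "gene"], 5)
  cat("  most rewired:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Rewiring score of one node in a merged network
#'
#' @param merged A `merged_network` from [merge_networks()].
#' @param node Gene symbol present in the merged network.
#' @return List with `dn` and `dn_corrected`.
#' @export
rewiring_score <- function(merged, node) {
  stopifnot(inherits(merged, "merged_network"))
  i <- match(node, merged$nodes$gene)
  if (is.na(i)) stop_dcornet("node not in merged network: ", node)
  list(dn = merged$nodes$rewiring_dn[i],
       dn_corrected = merged$nodes$rewiring_dn_corrected[i])
}

#' Nodes ranked by betweenness variation between conditions
#'
#' `betweenness_delta = |betweenness_A - betweenness_B|`, absent nodes
#' counting 0; sorted descending, rank 1 = largest change, ties share the
#' minimum rank.
#'
#' @param merged A `merged_network`.
#' @return data.frame `gene`, `betweenness_A`, `betweenness_B`,
#'   `betweenness_delta`, `rank`.
#' @export
betweenness_variation <- function(merged) {
  stopifnot(inherits(merged, "merged_network"))
  df <- merged$nodes[, c("gene", "betweenness_A", "betweenness_B",
                         "betweenness_delta")]
  df$rank <- rank_desc_min(df$betweenness_delta)
  df[order(-df$betweenness_delta, df$gene), , drop = FALSE]
}

#' Side-by-side comparison of two topology reports
#'
#' Tabulates every global metric for both condition networks with the
#' difference (B minus A), and, for edges present in both networks, the
#' movement of their edge-betweenness rank. The rank shift is
#' `rank_A - rank_B`, so a positive shift means the edge became more central
#' in condition B (e.g. a bottom-ranked edge in BRAF wt rising to the top in
#' BRAF V600E).
#'
#' @param report_A,report_B `topology_report` objects.
#' @return List with `global` (data.frame metric/A/B/difference) and
#'   `edges` (shared edges with ranks in both networks and `rank_shift`).
#' @export
compare_reports <- function(report_A, report_B) {
  stopifnot(inherits(report_A, "topology_report"),
            inherits(report_B, "topology_report"))
  metrics <- names(report_A$global)
  global <- data.frame(
    metric = metrics,
    A = as.numeric(unlist(report_A$global[metrics])),
    B = as.numeric(unlist(report_B$global[metrics])),
    stringsAsFactors = FALSE)
  global$difference <- global$B - global$A

  key <- function(df) paste(pmin(df$gene_a, df$gene_b),
                            pmax(df$gene_a, df$gene_b), sep = "|")
  eA <- report_A$edges; eB <- report_B$edges
  kA <- key(eA); kB <- key(eB)
  shared <- intersect(kA, kB)
  iA <- match(shared, kA); iB <- match(shared, kB)
  edges <- data.frame(
    gene_a = eA$gene_a[iA], gene_b = eA$gene_b[iA],
    betweenness_A = eA$betweenness[iA], betweenness_B = eB$betweenness[iB],
    rank_A = eA$rank[iA], rank_B = eB$rank[iB],
    stringsAsFactors = FALSE)
  edges$rank_shift <- edges$rank_A - edges$rank_B
  edges <- edges[order(-abs(edges$rank_shift), edges$gene_a, edges$gene_b), ,
                 drop = FALSE]
  list(global = global, edges = edges)
}
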
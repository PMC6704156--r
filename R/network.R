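new_cor_network <- function(graph, threshold, node_policy, n_samples) {
  structure(list(graph = graph, threshold = threshold,
                 node_policy = node_policy, n_samples = n_samples),
            class = "cor_network")
}

#' Build a correlation network by absolute-rho thresholding
#'
#' An undirected simple graph with an edge between genes i and j whenever
#' `|rho_ij| >= threshold`. Edges carry the signed correlation (`rho`) and
#' its magnitude (`abs_rho`); topology downstream treats the graph as
#' unweighted.
#'
#' @param corr A `cor_panel` from [correlation_matrix()], or a symmetric
#'   correlation matrix with dimnames.
#' @param threshold Absolute-correlation cutoff in `(0, 1]`.
#' @param node_policy `"nonisolated"` (default; only genes retaining at
#'   least one edge become nodes, mirroring how correlation networks are
#'   drawn) or `"all"` (every panel gene is a node, possibly isolated).
#' @return A `cor_network` object wrapping an igraph graph.
#' @export
build_network <- function(corr, threshold, node_policy = c("nonisolated", "all")) {
  node_policy <- match.arg(node_policy)
  rho <- if (inherits(corr, "cor_panel")) corr$rho else corr
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !(threshold > 0 && threshold <= 1)) {
    stop_dcornet("threshold must be in (0, 1]")
  }
  genes <- rownames(rho)
  ut <- which(upper.tri(rho) & abs(rho) >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = genes[ut[, 1]], to = genes[ut[, 2]],
                      rho = rho[ut], stringsAsFactors = FALSE)
  vertices <- if (node_policy == "all") data.frame(name = genes) else
    data.frame(name = genes[genes %in% c(edges$from, edges$to)])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  n_samp <- if (inherits(corr, "cor_panel")) corr$n_samples else NA_integer_
  new_cor_network(g, threshold = threshold, node_policy = node_policy,
                  n_samples = n_samp)
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf("Correlation network: %d nodes, %d edges (|rho| >= %s, %s nodes)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$threshold), x$node_policy))
  invisible(x)
}

# Is the thresholded graph a single connected piece under the policy?
is_unfragmented <- function(rho, threshold, node_policy) {
  genes <- rownames(rho)
  adj <- abs(rho) >= threshold
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  if (node_policy == "strict") {
    if (any(deg == 0)) return(FALSE)
    keep <- seq_along(genes)
  } else {
    keep <- which(deg > 0)
    if (length(keep) == 0) return(FALSE)
  }
  sub <- adj[keep, keep, drop = FALSE]
  # BFS from the first kept node
  seen <- logical(length(keep)); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(sub[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Highest non-fragmenting correlation threshold
#'
#' Scans the grid `grid_step, 2*grid_step, ..., 1` from the top down and
#' returns the largest threshold at which the network is still a single
#' connected component. "Fragmented" depends on the node policy:
#' `"nonisolated"` (default) requires one component among the genes that
#' retain at least one edge (isolated genes are ignored, as they are when a
#' correlation network is drawn); `"strict"` additionally requires every
#' panel gene to be reachable.
#'
#' @param corr A `cor_panel` or correlation matrix.
#' @param grid_step Grid resolution (default 0.01).
#' @param node_policy `"nonisolated"` or `"strict"`.
#' @return The selected threshold. If no grid value yields a connected
#'   network, returns `grid_step` with a warning.
#' @export
select_max_connected_threshold <- function(corr, grid_step = 0.01,
                                           node_policy = c("nonisolated", "strict")) {
  node_policy <- match.arg(node_policy)
  rho <- if (inherits(corr, "cor_panel")) corr$rho else corr
  stopifnot(is.matrix(rho), nrow(rho) >= 2)
  if (!(grid_step > 0 && grid_step < 1)) stop_dcornet("grid_step must be in (0, 1)")
  grid <- round(seq(grid_step, 1, by = grid_step), 10)
  for (t in rev(grid)) {
    if (is_unfragmented(rho, t, node_policy)) return(t)
  }
  warning("no grid threshold yields a non-fragmented network; returning grid_step",
          call. = FALSE)
  grid[1]
}
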
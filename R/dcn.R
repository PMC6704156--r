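#' Differential correlation network analysis of a stratified cohort
#'
#' The package's central entry point. Given a genes-by-samples expression
#' matrix, a sample annotation table and a gene panel, `dcn()` runs the full
#' two-condition comparison: optional Ward stratification of the cohort on a
#' signature gene set, per-condition Spearman correlation matrices over the
#' panel, absolute-correlation thresholding (with the automatic highest
#' non-fragmenting threshold unless a fixed one is given), the topology
#' metric suite for each condition network, and the merged-network rewiring
#' comparison.
#'
#' @param expr Expression matrix (genes x samples).
#' @param annotations data.frame with `sample_id` and the condition column
#'   (see [read_annotations_tsv()]).
#' @param panel Character vector of panel gene symbols used for the
#'   correlation networks (default: all genes in `expr`).
#' @param signature Optional signature gene set; if given, samples are
#'   stratified high/low by [ward_cluster_samples()].
#' @param condition Name of the annotation column defining the two
#'   conditions (default `"braf_status"`).
#' @param conditions Length-2 character vector naming condition A and
#'   condition B (default `c("wt", "V600E")`).
#' @param threshold Fixed absolute-correlation cutoff in `(0, 1]`, or `NULL`
#'   (default) to auto-select per condition.
#' @param grid_step Grid resolution for the automatic threshold.
#' @param node_policy Connectivity policy, `"nonisolated"` or `"strict"`
#'   (see [select_max_connected_threshold()]).
#' @param zscore Z-score signature genes before stratification.
#' @return A `dcn` object: list with `stratification` (or `NULL`),
#'   `correlations`, `networks`, `topology` (per condition),
#'   `merged`, `comparison`, `conditions`, `n_samples`, `call`.
#' @examples
#' design <- default_block_design()
#' cohort <- generate_cohort(design$blocks_A, design$blocks_B,
#'                           n_per_condition = 100,
#'                           signature_genes = design$signature_genes,
#'                           seed = 7)
#' fit <- dcn(cohort$expr, cohort$annotations, threshold = 0.5)
#' fit
#' head(summary(fit)$most_rewired)
#' @export
dcn <- function(expr, annotations, panel = NULL, signature = NULL,
                condition = "braf_status", conditions = c("wt", "V600E"),
                threshold = NULL, grid_step = 0.01,
                node_policy = c("nonisolated", "strict"), zscore = TRUE) {
  node_policy <- match.arg(node_policy)
  stopifnot(is.matrix(expr), is.data.frame(annotations),
            length(conditions) == 2)
  if (!condition %in% names(annotations)) {
    stop_dcornet("annotation table has no column ", dQuote(condition))
  }
  annotations <- annotations[annotations$sample_id %in% colnames(expr), , drop = FALSE]

  strat <- NULL
  if (!is.null(signature)) {
    strat <- ward_cluster_samples(expr, signature, zscore = zscore)
  }

  cond_samples <- lapply(conditions, function(v) {
    ids <- annotations$sample_id[annotations[[condition]] == v]
    if (length(ids) == 0) {
      stop_dcornet("no samples with ", condition, " = ", dQuote(v))
    }
    ids
  })
  names(cond_samples) <- conditions

  correlations <- lapply(cond_samples, function(ids) {
    correlation_matrix(subset_expression(expr, genes = panel, samples = ids))
  })

  # map build_network's "all" onto the strict connectivity policy
  build_policy <- if (node_policy == "strict") "all" else "nonisolated"
  networks <- lapply(correlations, function(cp) {
    t_used <- threshold %||%
      select_max_connected_threshold(cp, grid_step = grid_step,
                                     node_policy = node_policy)
    build_network(cp, threshold = t_used, node_policy = build_policy)
  })

  topo <- lapply(networks, topology_report)
  merged <- merge_networks(networks[[1]], networks[[2]])
  comparison <- compare_reports(topo[[1]], topo[[2]])

  structure(list(stratification = strat, correlations = correlations,
                 networks = networks, topology = topo, merged = merged,
                 comparison = comparison, conditions = conditions,
                 condition_field = condition,
                 n_samples = lengths(cond_samples), call = match.call()),
            class = "dcn")
}

#' @export
print.dcn <- function(x, ...) {
  cat("Differential correlation network analysis\n")
  cat("  conditions:", x$conditions[1], "(A,", x$n_samples[1], "samples) vs",
      x$conditions[2], "(B,", x$n_samples[2], "samples)\n")
  for (i in 1:2) {
    nt <- x$networks[[i]]
    cat(sprintf("  %s network: %d nodes, %d edges at |rho| >= %s\n",
                x$conditions[i], igraph::vcount(nt$graph),
                igraph::ecount(nt$graph), format(nt$threshold)))
  }
  ec <- x$merged$edge_counts
  cat("  merged:", ec[["both"]], "shared /", ec[["A_only"]], "A-only /",
      ec[["B_only"]], "B-only edges\n")
  if (!is.null(x$stratification)) {
    tab <- table(x$stratification$labels)
    cat("  stratification:", tab[["high"]], "signature-high /",
        tab[["low"]], "signature-low samples\n")
  }
  invisible(x)
}

#' Summarize a differential correlation network analysis
#'
#' @param object A `dcn` object.
#' @param top Number of top rewired nodes / moved edges to retain.
#' @param ... Unused.
#' @return A `summary.dcn`: global metric comparison, most-rewired nodes by
#'   Dn score, largest betweenness changes, largest edge-rank shifts.
#' @export
summary.dcn <- function(object, top = 10, ...) {
  nd <- object$merged$nodes
  most_rewired <- nd[order(-nd$rewiring_dn, nd$gene),
                     c("gene", "degree_A", "degree_B",
                       "rewiring_dn", "rewiring_dn_corrected")]
  structure(list(conditions = object$conditions,
                 global = object$comparison$global,
                 most_rewired = utils::head(most_rewired, top),
                 betweenness_variation =
                   utils::head(betweenness_variation(object$merged), top),
                 edge_rank_shifts = utils::head(object$comparison$edges, top)),
            class = "summary.dcn")
}

#' @export
print.summary.dcn <- function(x, ...) {
  cat("Global topology (A =", x$conditions[1], ", B =", x$conditions[2], "):\n")
  print(x$global, row.names = FALSE, digits = 4)
  cat("\nMost rewired nodes (Dn score):\n")
  print(x$most_rewired, row.names = FALSE, digits = 4)
  cat("\nLargest node-betweenness changes:\n")
  print(x$betweenness_variation, row.names = FALSE, digits = 4)
  if (nrow(x$edge_rank_shifts)) {
    cat("\nLargest edge-betweenness rank shifts (positive = more central in B):\n")
    print(x$edge_rank_shifts, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot the merged differential network
#'
#' Draws the union graph with edges coloured by class (shared / A-only /
#' B-only) and node size scaled by the Dn rewiring score — the usual visual
#' summary of a two-state network comparison.
#'
#' @param x A `dcn` object.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.dcn <- function(x, ...) {
  g <- x$merged$graph
  pal <- c(both = "#b9a7d6", A_only = "#e78ac3", B_only = "#66c2a5")
  ecol <- pal[igraph::E(g)$class]
  dn <- x$merged$nodes$rewiring_dn[match(igraph::V(g)$name, x$merged$nodes$gene)]
  size <- 6 + 8 * dn / max(dn, 1e-9)
  red <- dn / max(dn, 1e-9)
  vcol <- grDevices::rgb(1, 1 - 0.8 * red, 1 - 0.8 * red)
  set.seed(1)  # reproducible layout only
  igraph::plot.igraph(g, edge.color = ecol, vertex.size = size,
                      vertex.color = vcol, vertex.label.cex = 0.7, ...)
  graphics::legend("topleft", bty = "n",
                   legend = c("shared", paste0(x$conditions[1], " only"),
                              paste0(x$conditions[2], " only")),
                   col = pal, lwd = 2)
  invisible(x)
}
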
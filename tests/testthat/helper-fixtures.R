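# Fixture builders, generated in code at test time.

# A correlation matrix with |rho| = strength on the listed unordered pairs
# (gene-name pairs), 0 elsewhere.
rho_from_edges <- function(genes, edges, strength = 0.8) {
  p <- length(genes)
  rho <- diag(p)
  dimnames(rho) <- list(genes, genes)
  if (length(edges) > 0) {
    for (e in edges) {
      st <- if (length(strength) > 1) strength[[which(vapply(edges, identical, logical(1), e))]] else strength
      rho[e[1], e[2]] <- rho[e[2], e[1]] <- st
    }
  }
  rho
}

# cor_network fixture from explicit edges (all |rho| >= 0.5 by construction).
net_from_edges <- function(genes, edges, strength = 0.8) {
  build_network(rho_from_edges(genes, edges, strength), threshold = 0.5,
                node_policy = "nonisolated")
}

# adjacency matrix of a cor_network (for the oracles)
adjacency_of <- function(network) {
  g <- network$graph
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  a
}

# random connected-ish graph as a cor_network over n nodes
random_fixture_network <- function(n, p_edge = 0.4, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(genes, 2, simplify = FALSE)
  edges <- pairs[stats::runif(length(pairs)) < p_edge]
  while (length(edges) == 0) edges <- pairs[stats::runif(length(pairs)) < p_edge]
  net_from_edges(genes, edges)
}

write_expression_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small deterministic expression table: 4 genes x 6 samples
toy_expression <- function() {
  set.seed(42)
  vals <- matrix(stats::rnorm(24), 4, 6,
                 dimnames = list(c("IDO1", "KYNU", "KMO", "CD86"),
                                 sprintf("S%d", 1:6)))
  vals
}
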
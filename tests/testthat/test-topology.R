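path4 <- function() net_from_edges(letters[1:4],
                                   list(c("a", "b"), c("b", "c"), c("c", "d")))

test_that("textbook graphs give textbook global metrics", {
  g <- global_metrics(path4())
  expect_equal(g$density, 0.5)
  expect_equal(g$diameter, 3)
  expect_equal(g$radius, 2)
  expect_equal(g$avg_clustering_coefficient, 0)

  # star: 1 hub + 3 leaves, centralization (4/2) * (3/3 - 0.5) = 1
  star <- net_from_edges(letters[1:4],
                         list(c("a", "b"), c("a", "c"), c("a", "d")))
  gs <- global_metrics(star)
  expect_equal(gs$centralization, 1)
  expect_equal(gs$density, 0.5)

  # any k-regular graph has zero degree heterogeneity
  ring <- net_from_edges(letters[1:5],
                         list(c("a", "b"), c("b", "c"), c("c", "d"),
                              c("d", "e"), c("e", "a")))
  expect_equal(global_metrics(ring)$heterogeneity, 0)
  k4 <- net_from_edges(letters[1:4], utils::combn(letters[1:4], 2, simplify = FALSE))
  expect_equal(global_metrics(k4)$heterogeneity, 0)
  expect_equal(global_metrics(k4)$avg_clustering_coefficient, 1)
})

test_that("degree median uses the mean-of-central-order-statistics convention", {
  # degrees of the 4-path are 1,2,2,1 -> median 1.5 (a half-integer)
  expect_equal(global_metrics(path4())$degree_median, 1.5)
})

test_that("density times n(n-1)/2 equals the edge count exactly", {
  for (seed in 1:3) {
    net <- random_fixture_network(7, 0.4, seed)
    g <- global_metrics(net)
    expect_equal(g$density * g$n_nodes * (g$n_nodes - 1) / 2, g$n_edges)
  }
})

test_that("node betweenness equals the brute-force oracle", {
  p <- path4()
  bt <- node_betweenness(p)
  expect_equal(unname(bt[c("a", "b", "c", "d")]), c(0, 2, 2, 0))
  # 3-path: middle node mediates exactly one pair
  p3 <- net_from_edges(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  expect_equal(unname(node_betweenness(p3)[c("a", "b", "c")]), c(0, 1, 0))
  # complete graph: every pair adjacent, betweenness all zero
  k4 <- net_from_edges(letters[1:4], utils::combn(letters[1:4], 2, simplify = FALSE))
  expect_equal(unname(node_betweenness(k4)), rep(0, 4))

  for (seed in 4:8) {
    net <- random_fixture_network(sample(5:8, 1), 0.45, seed)
    adj <- adjacency_of(net)
    got <- node_betweenness(net)[rownames(adj)]
    expect_equal(unname(got), oracle_node_betweenness(adj), tolerance = 1e-12,
                 label = paste("seed", seed))
  }
})

test_that("edge betweenness and its ranking equal the brute-force oracle", {
  p3 <- net_from_edges(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  eb <- edge_betweenness_ranking(p3)
  # edge (a,b) carries pairs a-b and a-c
  ab <- eb[(eb$gene_a == "a" & eb$gene_b == "b") |
             (eb$gene_a == "b" & eb$gene_b == "a"), ]
  expect_equal(ab$betweenness, 2)

  # bridge between two triangles is rank 1
  genes <- c("a", "b", "c", "x", "y", "z")
  edges <- list(c("a", "b"), c("b", "c"), c("a", "c"),
                c("x", "y"), c("y", "z"), c("x", "z"), c("c", "x"))
  bridge_net <- net_from_edges(genes, edges)
  eb2 <- edge_betweenness_ranking(bridge_net)
  top <- eb2[eb2$rank == 1, ]
  expect_identical(sort(c(top$gene_a, top$gene_b)), c("c", "x"))

  for (seed in 11:14) {
    net <- random_fixture_network(6, 0.5, seed)
    adj <- adjacency_of(net)
    eb3 <- edge_betweenness_ranking(net)
    for (k in seq_len(nrow(eb3))) {
      u <- match(eb3$gene_a[k], rownames(adj))
      v <- match(eb3$gene_b[k], rownames(adj))
      expect_equal(eb3$betweenness[k], oracle_edge_betweenness(adj, u, v),
                   tolerance = 1e-12)
    }
    expect_identical(eb3$rank, as.integer(rank(-eb3$betweenness, ties.method = "min")))
  }
})

test_that("betweenness totals reconcile with shortest-path intermediaries", {
  for (seed in 21:23) {
    net <- random_fixture_network(7, 0.4, seed)
    adj <- adjacency_of(net)
    pc <- oracle_path_counts(adj)
    n <- nrow(adj)
    # sum over connected unordered pairs of the mean number of intermediate
    # nodes on their shortest paths equals total node betweenness
    total_expected <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (is.finite(pc$d[s, t])) total_expected <- total_expected + pc$d[s, t] - 1
    }
    expect_equal(sum(node_betweenness(net)), total_expected, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabelling", {
  net <- random_fixture_network(7, 0.45, 31)
  ed <- network_edges(net)
  genes <- igraph::V(net$graph)$name
  relab <- setNames(sprintf("R%02d", seq_along(genes)), genes)
  net2 <- net_from_edges(unname(relab),
                         lapply(seq_len(nrow(ed)), function(i)
                           unname(relab[c(ed$gene_a[i], ed$gene_b[i])])))
  g1 <- global_metrics(net)
  g2 <- global_metrics(net2)
  expect_equal(g1, g2)
  expect_equal(sort(unname(node_betweenness(net))),
               sort(unname(node_betweenness(net2))))
})

test_that("fragmented graphs report distances on the largest component", {
  genes <- c("a", "b", "c", "d", "e")
  net <- net_from_edges(genes, list(c("a", "b"), c("b", "c"), c("d", "e")))
  rep <- topology_report(net)
  expect_true(rep$fragmented)
  expect_equal(rep$global$diameter, 2)  # a-b-c component
  expect_equal(rep$global$radius, 1)
  expect_equal(rep$global$avg_shortest_path_length, 4 / 3)
  # mean over components: (4/3 + 1) / 2
  expect_equal(rep$global$avg_shortest_path_components, (4 / 3 + 1) / 2)
})

test_that("small graphs degrade gracefully", {
  pair <- net_from_edges(c("a", "b"), list(c("a", "b")))
  g <- global_metrics(pair)
  expect_true(is.na(g$centralization))  # undefined for n < 3
  expect_equal(g$density, 1)
  single <- build_network(rho_from_edges(c("a", "b"), list(), 0), 0.5, "all")
  expect_error(topology_report(structure(list(graph = igraph::induced_subgraph(
    single$graph, 1)), class = "cor_network")), "at least 2")
})

test_that("clustering average can exclude low-degree nodes", {
  # triangle plus pendant: local CCs 1, 1, 1/1? c has degree 3: neighbours
  # a,b,d with one realized link (a,b) of three -> 1/3; pendant d -> 0
  genes <- c("a", "b", "c", "d")
  net <- net_from_edges(genes, list(c("a", "b"), c("b", "c"), c("a", "c"),
                                    c("c", "d")))
  inc <- global_metrics(net)$avg_clustering_coefficient
  exc <- global_metrics(net, include_low_degree = FALSE)$avg_clustering_coefficient
  expect_equal(inc, (1 + 1 + 1 / 3 + 0) / 4)
  expect_equal(exc, (1 + 1 + 1 / 3) / 3)
})

test_that("Erdos-Renyi mean degree matches p(n-1) within 3 SE", {
  set.seed(77)
  n <- 200; p <- 0.05
  pairs <- utils::combn(n, 2)
  keep <- runif(ncol(pairs)) < p
  genes <- sprintf("g%03d", 1:n)
  edges <- lapply(which(keep), function(k) genes[pairs[, k]])
  net <- net_from_edges(genes, edges)
  # include isolated nodes: mean degree = 2E/n over all n vertices
  mean_deg <- 2 * igraph::ecount(net$graph) / n
  se <- sqrt(p * (1 - p) * (n - 1) / n) * sqrt(2)
  expect_lt(abs(mean_deg - p * (n - 1)), 3 * se)
})
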
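test_that("merging identical networks yields only shared edges and zero rewiring", {
  net <- random_fixture_network(6, 0.5, 41)
  mg <- merge_networks(net, net)
  expect_equal(unname(mg$edge_counts[c("A_only", "B_only")]), c(0, 0))
  expect_equal(mg$edge_counts[["both"]], igraph::ecount(net$graph))
  expect_equal(mg$nodes$rewiring_dn, rep(0, nrow(mg$nodes)))
  expect_equal(mg$nodes$betweenness_delta, rep(0, nrow(mg$nodes)))
  expect_equal(betweenness_variation(mg)$betweenness_delta,
               rep(0, nrow(mg$nodes)))
})

test_that("edge classes follow set algebra and reconcile exactly", {
  netA <- net_from_edges(c("a", "b", "c", "d"), list(c("a", "b"), c("b", "c")))
  netB <- net_from_edges(c("a", "b", "d"), list(c("a", "b"), c("b", "d")))
  mg <- merge_networks(netA, netB)
  cls <- setNames(igraph::E(mg$graph)$class,
                  apply(igraph::as_edgelist(mg$graph), 1, function(r)
                    paste(sort(r), collapse = "-")))
  expect_identical(cls[["a-b"]], "both")
  expect_identical(cls[["b-c"]], "A_only")
  expect_identical(cls[["b-d"]], "B_only")
  # conservation: |both| + |X_only| = |edges_X|
  expect_equal(mg$edge_counts[["both"]] + mg$edge_counts[["A_only"]],
               igraph::ecount(netA$graph))
  expect_equal(mg$edge_counts[["both"]] + mg$edge_counts[["B_only"]],
               igraph::ecount(netB$graph))
})

test_that("disjoint edge sets produce no shared edges", {
  netA <- net_from_edges(c("a", "b"), list(c("a", "b")))
  netB <- net_from_edges(c("c", "d"), list(c("c", "d")))
  mg <- merge_networks(netA, netB)
  expect_equal(mg$edge_counts[["both"]], 0)
  expect_equal(sum(mg$edge_counts), 2)
})

test_that("Dn rewiring scores follow the symmetric-difference formula", {
  # node b: 1 A-only (b-c) + 1 B-only (b-d), no shared change -> sqrt(2)
  netA <- net_from_edges(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  netB <- net_from_edges(c("a", "b", "d"), list(c("a", "b"), c("b", "d")))
  mg <- merge_networks(netA, netB)
  expect_equal(rewiring_score(mg, "b")$dn, sqrt(2))
  # identical neighbourhood -> 0 (node a keeps its single edge)
  expect_equal(rewiring_score(mg, "a")$dn, 0)
  expect_error(rewiring_score(mg, "zz"), "not in merged")

  # b = 4 lost edges, c = 0, a = 0: dn = 2, degree_A = 4, degree_B = 0,
  # dn_corrected = 2 / max(1, 2) = 1
  hub <- net_from_edges(c("h", "x1", "x2", "x3", "x4"),
                        list(c("h", "x1"), c("h", "x2"), c("h", "x3"), c("h", "x4")))
  lone <- net_from_edges(c("x1", "x2"), list(c("x1", "x2")))
  mg2 <- merge_networks(hub, lone)
  sc <- rewiring_score(mg2, "h")
  expect_equal(sc$dn, 2)
  expect_equal(sc$dn_corrected, 1)
})

test_that("dn and betweenness_delta are symmetric in A/B exchange", {
  netA <- random_fixture_network(7, 0.4, 51)
  netB <- random_fixture_network(7, 0.4, 52)
  m1 <- merge_networks(netA, netB)
  m2 <- merge_networks(netB, netA)
  expect_equal(m1$nodes$rewiring_dn, m2$nodes$rewiring_dn)
  expect_equal(m1$nodes$rewiring_dn_corrected, m2$nodes$rewiring_dn_corrected)
  expect_equal(m1$nodes$betweenness_delta, m2$nodes$betweenness_delta)
  expect_equal(m1$edge_counts[["A_only"]], m2$edge_counts[["B_only"]])
})

test_that("nodes absent from one condition are zero-filled for betweenness", {
  netA <- net_from_edges(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  netB <- net_from_edges(c("x", "y"), list(c("x", "y")))
  mg <- merge_networks(netA, netB)
  bv <- betweenness_variation(mg)
  b_row <- bv[bv$gene == "b", ]
  expect_equal(b_row$betweenness_A, 1)
  expect_equal(b_row$betweenness_B, 0)
  expect_equal(b_row$betweenness_delta, 1)
  expect_equal(bv$rank[1], 1)
})

test_that("report comparison tabulates metric differences and edge rank shifts", {
  net <- random_fixture_network(7, 0.45, 61)
  rep1 <- topology_report(net)
  cmp_same <- compare_reports(rep1, rep1)
  expect_equal(cmp_same$global$difference, rep(0, nrow(cmp_same$global)))
  expect_equal(cmp_same$edges$rank_shift, rep(0, nrow(cmp_same$edges)))

  # hand-built pair: shared edge a-b moves from rank r_A to r_B
  netA <- net_from_edges(c("a", "b", "c", "d"),
                         list(c("a", "b"), c("b", "c"), c("c", "d")))
  netB <- net_from_edges(c("a", "b", "c"), list(c("a", "b"), c("a", "c")))
  cmp <- compare_reports(topology_report(netA), topology_report(netB))
  shared <- cmp$edges[cmp$edges$gene_a == "a" & cmp$edges$gene_b == "b", ]
  # in A the path edge a-b has betweenness 3 (rank 2, middle edge b-c rank 1);
  # in B both edges tie at 2 and share rank 1 -> shift = 2 - 1 = +1
  expect_equal(shared$rank_A, 2)
  expect_equal(shared$rank_B, 1)
  expect_equal(shared$rank_shift, 1)
  nd <- cmp$global[cmp$global$metric == "n_edges", ]
  expect_equal(nd$difference, -1)
})

test_that("planted rewiring is recovered by the Dn ranking", {
  design <- default_block_design()
  recalls <- vapply(101:104, function(seed) {
    co <- generate_cohort(design$blocks_A, design$blocks_B,
                          n_per_condition = 300,
                          signature_genes = design$signature_genes, seed = seed)
    fit <- dcn(co$expr, co$annotations, threshold = 0.5)
    nd <- fit$merged$nodes
    rk <- rank(-nd$rewiring_dn, ties.method = "min")
    truth <- co$truth$rewired_genes
    mean(rk[match(truth, nd$gene)] <= 2 * length(truth))
  }, numeric(1))
  expect_gte(mean(recalls), 0.8)
  # and edge classes reconcile on one of the fits
  co <- generate_cohort(design$blocks_A, design$blocks_B, n_per_condition = 100,
                        signature_genes = design$signature_genes, seed = 105)
  fit <- dcn(co$expr, co$annotations, threshold = 0.5)
  ec <- fit$merged$edge_counts
  expect_equal(ec[["both"]] + ec[["A_only"]],
               igraph::ecount(fit$networks[[1]]$graph))
  expect_equal(ec[["both"]] + ec[["B_only"]],
               igraph::ecount(fit$networks[[2]]$graph))
})
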
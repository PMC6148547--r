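g_from_edges <- function(df, nodes = NULL) ppi_graph(df, nodes = nodes)

test_that("the confidence filter keeps 0.70 and drops 0.69, preserving nodes", {
  ed <- data.frame(node_a = c("a", "a", "b"), node_b = c("b", "c", "c"),
                   score = c(0.69, 0.70, 0.95))
  g <- filter_edges(g_from_edges(ed))
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::vcount(g), 3)
  kept <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_false("a-b" %in% kept)
  # empty graph passes through
  e0 <- filter_edges(g_from_edges(ed[0, ], nodes = "x"))
  expect_equal(igraph::ecount(e0), 0)
  # STRING integer dialect: 700 parses as 0.700 and survives
  ed2 <- data.frame(node_a = "a", node_b = "b", score = 700)
  expect_equal(igraph::ecount(filter_edges(g_from_edges(ed2))), 1)
})

test_that("main_component picks the largest component with declared ties", {
  ed <- data.frame(node_a = c("a", "b", "c", "d", "x", "y"),
                   node_b = c("b", "c", "d", "e", "y", "z"),
                   score = 1)
  g <- g_from_edges(ed)
  mc <- main_component(g)
  expect_setequal(igraph::V(mc)$name, c("a", "b", "c", "d", "e"))
  # connected graph unchanged
  expect_equal(igraph::vcount(main_component(mc)), 5)
  # size tie: more edges wins
  ed2 <- data.frame(node_a = c("a", "b", "c", "x", "y", "z", "x"),
                    node_b = c("b", "c", "a", "y", "z", "x", "z"),
                    score = 1)  # triangle with a duplicate edge collapses; use K3 vs path
  ed3 <- data.frame(node_a = c("a", "b", "c", "x", "y"),
                    node_b = c("b", "c", "a", "y", "z"),
                    score = 1)
  mc3 <- main_component(g_from_edges(ed3))
  expect_setequal(igraph::V(mc3)$name, c("a", "b", "c"))  # 3 edges beat 2
})

test_that("the degree/betweenness core obeys strict means (star, regular)", {
  # regular graph: everyone equals the mean, strict rule empties the core
  ring <- data.frame(node_a = c("a", "b", "c", "d"),
                     node_b = c("b", "c", "d", "a"), score = 1)
  expect_error(degree_betweenness_core(g_from_edges(ring)), "empty core")
  # star: only the center exceeds both means
  star <- data.frame(node_a = "hub", node_b = paste0("s", 1:4), score = 1)
  core <- degree_betweenness_core(g_from_edges(star))
  expect_identical(igraph::V(core)$name, "hub")
  expect_equal(igraph::graph_attr(core, "mean_degree"), 8 / 5)
  # the printed mean degree of a (579, 1716) graph
  expect_equal(2 * 1716 / 579, 5.928, tolerance = 5e-4)
})

test_that("small named graphs give the hand-enumerated centrality values", {
  path3 <- g_from_edges(data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                                   score = 1))
  ct <- centralities(path3, epc_rep = 10)
  b <- which(ct$node == "b")
  expect_equal(ct$Degree[b], 2)
  expect_equal(ct$Betweenness[b], 1)
  expect_equal(ct$Stress[b], 1)
  expect_equal(ct$Closeness[b], 1)

  tri <- g_from_edges(data.frame(node_a = c("a", "a", "b"),
                                 node_b = c("b", "c", "c"), score = 1))
  ct2 <- centralities(tri, epc_rep = 10)
  expect_equal(ct2$MCC, rep(2, 3))            # (3-1)! per node
  expect_equal(ct2$MNC, rep(2, 3))
  expect_equal(ct2$DMNC, rep(1 / 2^1.7, 3))   # 0.3078
  expect_equal(ct2$ClusteringCoefficient, rep(1, 3))

  star <- g_from_edges(data.frame(node_a = "hub", node_b = paste0("s", 1:4),
                                  score = 1))
  ct3 <- centralities(star, epc_rep = 10)
  expect_equal(ct3$MNC[ct3$node == "hub"], 1)  # leaves induce no edges
  expect_equal(ct3$DMNC[ct3$node == "hub"], 0)

  expect_error(centralities(g_from_edges(data.frame(
    node_a = c("a", "x"), node_b = c("b", "y"), score = 1))), "connected")
})

test_that("centralities match brute-force oracles on exhaustive small graphs", {
  graphs <- c(all_connected_graphs(4), all_connected_graphs(5)[seq(1, 728, by = 8)])
  set.seed(31)
  for (n in 6:8) {
    graphs <- c(graphs, lapply(1:6, function(i) random_connected_graph(n, 0.45)))
  }
  for (g in graphs) {
    A <- adj_matrix(g)
    ct <- centralities(g, epc_rep = 2)
    oracle <- brute_centralities(A)
    for (what in names(oracle)) {
      expect_equal(ct[[what]], unname(oracle[[what]]), tolerance = 1e-10,
                   info = what)
    }
    nd <- brute_mnc_dmnc(A)
    expect_equal(ct$MNC, nd$MNC)
    expect_equal(ct$DMNC, nd$DMNC, tolerance = 1e-10)
    expect_equal(ct$BottleNeck, unname(brute_bottleneck(A)))
  }
})

test_that("MCC matches brute-force maximal-clique enumeration up to 10 nodes", {
  set.seed(32)
  graphs <- c(all_connected_graphs(4)[seq(1, 38, by = 3)],
              lapply(c(6, 7, 8, 9, 10), function(n) random_connected_graph(n, 0.5)))
  for (g in graphs) {
    ct <- centralities(g, epc_rep = 2)
    expect_equal(ct$MCC, unname(brute_mcc(adj_matrix(g))))
  }
})

test_that("EPC is seed-deterministic and stable across resample sets", {
  set.seed(33)
  g <- random_connected_graph(50, 0.25)
  a <- centralities(g, epc_rep = 1000, epc_seed = 5)$EPC
  b <- centralities(g, epc_rep = 1000, epc_seed = 5)$EPC
  expect_identical(a, b)
  c2 <- centralities(g, epc_rep = 1000, epc_seed = 6)$EPC
  expect_false(identical(a, c2))
  expect_true(all(abs(a - c2) / pmax(a, c2) < 0.02))  # 2% relative stability
})

test_that("consensus hub voting counts membership with boundary ties included", {
  # 25 nodes; score ties straddling the 20th place are all included
  tab <- data.frame(node = sprintf("n%02d", 1:25),
                    A = c(rep(10, 19), rep(5, 3), 1, 1, 1),
                    B = 25:1)
  hubs <- consensus_hubs(tab, top_k = 20, min_count = 2)
  # algorithm A keeps 22 nodes: 19 at score 10 plus all three tied at the
  # 20th score (5); algorithm B keeps its plain top 20
  expect_true(all(hubs$count[hubs$gene %in% sprintf("n%02d", 1:20)] == 2L))
  expect_true(all(hubs$count[hubs$gene %in% c("n21", "n22")] == 1L))
  expect_true(all(hubs$count[hubs$gene %in% c("n23", "n24", "n25")] == 0L))
  # node in exactly one list is excluded from hubs
  one_list <- hubs$gene[hubs$count == 1]
  expect_true(all(!hubs$hub[hubs$gene %in% one_list]))
  # permutation equivariance in node labels
  perm <- sample(25)
  tab2 <- tab[perm, ]
  hubs2 <- consensus_hubs(tab2, top_k = 20, min_count = 2)
  m <- match(hubs$gene, hubs2$gene)
  expect_identical(hubs$count, hubs2$count[m])
  # a node top-ranked by all algorithms gets the full count
  tab3 <- data.frame(node = c("best", "x", "y"), A = c(3, 2, 1), B = c(9, 1, 2))
  expect_identical(consensus_hubs(tab3, top_k = 1)$count[1], 2L)
})

test_that("the planted near-clique module is recovered as consensus hubs", {
  rec <- vapply(1:5, function(s) {
    cfg <- synthetic_config(seed = 500 + s)
    ppi <- gen_ppi(cfg)
    g <- main_component(filter_edges(ppi_graph(ppi$edges)))
    core <- main_component(degree_betweenness_core(g))
    ct <- centralities(core, epc_rep = 200, epc_seed = s)
    hubs <- consensus_hubs(ct)
    mean(ppi$truth$module %in% hubs$gene[hubs$hub])
  }, numeric(1))
  expect_gte(mean(rec), 0.8)
})
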
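test_that("subnetwork extraction honours order and score filtering", {
  edges <- data.frame(node_a = c("A", "A", "B"), node_b = c("B", "C", "C"),
                      score = c(0.95, 0.92, 0.91))
  # first-order star: seed A pulls in B, C and the B-C edge
  net <- buildSubnetwork("A", edges, min_score = 0.9, order = "first")
  expect_equal(igraph::vcount(networkGraph(net)), 3L)
  expect_equal(igraph::ecount(networkGraph(net)), 3L)
  # zero-order on {A, B} drops the absent C and keeps only A-B
  net0 <- buildSubnetwork(c("A", "B"), edges, min_score = 0.9,
                          order = "zero")
  expect_setequal(nodeTable(net0)$gene, c("A", "B"))
  expect_equal(igraph::ecount(networkGraph(net0)), 1L)
  # zero-order seeds joined only through a non-seed have no edges
  edges2 <- data.frame(node_a = c("A", "C"), node_b = c("C", "B"),
                       score = c(0.95, 0.95))
  net00 <- buildSubnetwork(c("A", "B"), edges2, order = "zero")
  expect_equal(igraph::ecount(networkGraph(net00)), 0L)
  expect_true(all(nodeTable(net00)$isolated))
  expect_error(buildSubnetwork("ZZZ", edges), "none of the seed")
  # score filter removes low-confidence edges
  netf <- buildSubnetwork("A", edges, min_score = 0.93, order = "first")
  expect_equal(igraph::ecount(networkGraph(netf)), 1L)
})

test_that("degree and betweenness match hand values on canonical graphs", {
  path <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                     score = 1)
  net <- addCentralities(buildSubnetwork(c("a", "b", "c"), path,
                                         min_score = 0, order = "zero"))
  nt <- nodeTable(net)
  expect_equal(nt$betweenness[nt$gene == "b"], 1)
  expect_equal(nt$betweenness[nt$gene == "a"], 0)
  expect_equal(nt$degree[nt$gene == "b"], 2L)

  star <- data.frame(node_a = "c", node_b = c("l1", "l2", "l3"), score = 1)
  nets <- addCentralities(buildSubnetwork("c", star, min_score = 0))
  nts <- nodeTable(nets)
  expect_equal(nts$betweenness[nts$gene == "c"], 3)  # C(3,2) leaf pairs

  tri <- data.frame(node_a = c("x", "y", "x"), node_b = c("y", "z", "z"),
                    score = 1)
  nett <- addCentralities(buildSubnetwork(c("x", "y", "z"), tri,
                                          min_score = 0, order = "zero"))
  expect_equal(nodeTable(nett)$betweenness, rep(0, 3))
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    full <- t(combn(n, 2))
    pick <- full[runif(nrow(full)) < 0.45, , drop = FALSE]
    if (nrow(pick) < 2) next
    edges <- data.frame(node_a = paste0("v", pick[, 1]),
                        node_b = paste0("v", pick[, 2]), score = 1)
    net <- addCentralities(buildSubnetwork(paste0("v", 1:n), edges,
                                           min_score = 0, order = "zero"))
    nt <- nodeTable(net)
    oracle <- betweennessOracle(pick, n)
    # vertices incident to no edge are absent from the subnetwork
    present <- intersect(paste0("v", 1:n), nt$gene)
    expect_equal(nt$betweenness[match(present, nt$gene)],
                 oracle[as.integer(sub("v", "", present))],
                 tolerance = 1e-9)
    # handshake identity
    expect_equal(sum(nt$degree), 2L * igraph::ecount(networkGraph(net)))
  }
})

test_that("hub ranking breaks ties by betweenness then symbol", {
  g <- igraph::make_empty_graph(n = 4, directed = FALSE)
  net <- new("InteractionNetwork", graph = g,
             nodes = S4Vectors::DataFrame(
               gene = c("d", "b", "a", "c"),
               is_seed = TRUE,
               degree = c(5L, 3L, 3L, 1L),
               betweenness = c(9, 7, 2, 0)))
  hubs <- rankHubs(net, k = 4L)
  expect_equal(hubs$gene, c("d", "b", "a", "c"))
  expect_warning(rankHubs(net, k = 10L), "node count")
  expect_error(rankHubs(new("InteractionNetwork", graph = g,
                            nodes = S4Vectors::DataFrame(
                              gene = letters[1:4], is_seed = TRUE)),
                        k = 2), "addCentralities")
})

test_that("hub ranking is stable under permutations of the edge file", {
  set.seed(31)
  cfg <- simulationConfig(n_genes = 150, n_de_up = 25, n_de_down = 25,
                          r_true = 3, n_samples_per_group = c(4, 4),
                          network_n_nodes = 100, network_hub_degree = 12,
                          n_hubs = 4, seed = 19)
  sim <- simulateExpression(cfg)
  edges <- simulateNetwork(cfg, sim$truth)
  seeds <- c(sim$truth@de_up, sim$truth@de_down)
  h1 <- rankHubs(addCentralities(
    buildSubnetwork(seeds, edges, min_score = 0.5)), k = 8)
  perm <- edges[sample(nrow(edges)), ]
  h2 <- rankHubs(addCentralities(
    buildSubnetwork(seeds, perm, min_score = 0.5)), k = 8)
  expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("bipartite reports respect min_shared and rank TFs by centrality", {
  assoc <- data.frame(gene = c("g1", "g2", "g3", "g1", "g2"),
                      entity = c("D", "D", "D", "E", "E"),
                      score = c(0.9, 0.8, 0.7, 0.9, 0.2))
  rep2 <- bipartiteReport(c("g1", "g2"), assoc, min_shared = 2)
  expect_setequal(rep2$entity, c("D", "E"))
  expect_equal(rep2$genes[rep2$entity == "D"], "g1,g2")
  rep3 <- bipartiteReport(c("g1", "g2"), assoc, min_shared = 3)
  expect_equal(nrow(rep3), 0L)
  # score filter removes weak associations before counting
  repf <- bipartiteReport(c("g1", "g2"), assoc, min_score = 0.5,
                          min_shared = 2)
  expect_false("E" %in% repf$entity)
  # TF convention: rank by bipartite degree then betweenness
  tf <- data.frame(gene = c("g1", "g2", "g3", "g1"),
                   entity = c("TF1", "TF1", "TF1", "TF2"),
                   score = 1)
  rtf <- bipartiteReport(c("g1", "g2", "g3"), tf, min_shared = 1,
                         rank_by_centrality = TRUE)
  expect_equal(rtf$entity[1], "TF1")
  expect_equal(rtf$degree[1], 3L)
})

test_that("planted hubs dominate the simulated interactome", {
  cfg <- simulationConfig(n_genes = 300, n_de_up = 50, n_de_down = 50,
                          r_true = 4, n_samples_per_group = c(4, 4),
                          network_n_nodes = 200, network_hub_degree = 20,
                          n_hubs = 5, seed = 23)
  sim <- simulateExpression(cfg)
  edges <- simulateNetwork(cfg, sim$truth)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  expect_true(all(igraph::degree(g)[sim$truth@hubs] >= 20))
  # simple graph: no loops or duplicate edges
  expect_true(igraph::is_simple(g))
  # identical edge list under the same seed
  expect_identical(edges, simulateNetwork(cfg, sim$truth))
  seeds <- c(sim$truth@de_up, sim$truth@de_down)
  hubs <- rankHubs(addCentralities(buildSubnetwork(seeds, edges)), k = 5)
  expect_setequal(hubs$gene, sim$truth@hubs)
})
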
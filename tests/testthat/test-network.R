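test_that("a minimal H-C-T chain builds with 3 nodes and 2 edges", {
  net <- build_network("H1", "C1", "T1",
                       data.frame(herb = "H1", compound = "C1"),
                       data.frame(compound = "C1", target = "T1"))
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$kind, c("herb-compound", "compound-target"))
})

test_that("edges with undeclared endpoints are integrity errors naming them", {
  expect_error(
    build_network("H1", "C1", "T1",
                  data.frame(herb = "H9", compound = "C1"),
                  data.frame(compound = "C1", target = "T1")),
    "undeclared herb.*H9")
  expect_error(
    build_network("H1", "C1", "T1",
                  data.frame(herb = "H1", compound = "C1"),
                  data.frame(compound = "C1", target = "Tx")),
    "undeclared target.*Tx")
})

test_that("node ids must be unique across types; tripartite form is structural", {
  expect_error(
    build_network("X", "X", "T1",
                  data.frame(herb = "X", compound = "X"),
                  data.frame(compound = "X", target = "T1")),
    "unique across")
  # the constructor only accepts herb-compound and compound-target pairs, so
  # any built network is tripartite by construction
  tri <- random_tripartite(5)$net
  expect_setequal(unique(tri$edges$kind), c("herb-compound", "compound-target"))
  herb_ids <- tri$nodes$id[tri$nodes$type == "herb"]
  target_ids <- tri$nodes$id[tri$nodes$type == "target"]
  expect_false(any(tri$edges$from %in% herb_ids & tri$edges$to %in% target_ids))
})

test_that("pruning drops isolated nodes only", {
  net <- build_network(c("H1", "H2"), c("C1", "C2"), "T1",
                       data.frame(herb = "H1", compound = "C1"),
                       data.frame(compound = "C1", target = "T1"),
                       prune_isolated = TRUE)
  expect_setequal(net$nodes$id, c("H1", "C1", "T1"))
})

test_that("degree obeys the handshake lemma and matches incidence counts", {
  for (seed in 1:8) {
    rt <- random_tripartite(seed, n_h = 3, n_c = 8, n_t = 9)
    ct <- centrality_table(rt$net)
    expect_equal(sum(ct$degree), 2L * nrow(rt$net$edges))
    manual <- vapply(ct$node_id, function(v) {
      sum(rt$net$edges$from == v) + sum(rt$net$edges$to == v)
    }, integer(1))
    expect_equal(ct$degree, unname(manual))
  }
})

test_that("star centre degree equals leaf count", {
  k <- 7
  net <- build_network(character(), "hub", paste0("t", 1:k),
                       data.frame(herb = character(), compound = character()),
                       data.frame(compound = "hub", target = paste0("t", 1:k)))
  ct <- centrality_table(net)
  expect_equal(ct$degree[ct$node_id == "hub"], k)
})

test_that("path midpoint has raw betweenness 1; endpoints 0", {
  net <- build_network("a", "b", "c",
                       data.frame(herb = "a", compound = "b"),
                       data.frame(compound = "b", target = "c"))
  ct <- centrality_table(net, normalized = FALSE)
  expect_equal(ct$betweenness[ct$node_id == "b"], 1)
  expect_equal(ct$betweenness[ct$node_id %in% c("a", "c")], c(0, 0))
})

test_that("betweenness matches the exhaustive shortest-path oracle", {
  for (seed in 1:10) {
    rt <- random_tripartite(seed, n_h = 2, n_c = 6, n_t = 6,
                            p_attr = 0.5, p_int = 0.35)
    ct <- centrality_table(rt$net, normalized = FALSE)
    oracle <- brute_betweenness(rt$nodes, rt$edges)
    expect_equal(ct$betweenness, unname(oracle[ct$node_id]), tolerance = 1e-10)
  }
})

test_that("normalized betweenness divides by (n-1)(n-2)/2 over all nodes", {
  rt <- random_tripartite(3, n_h = 2, n_c = 5, n_t = 5)
  n <- nrow(rt$net$nodes)
  raw <- centrality_table(rt$net, normalized = FALSE)$betweenness
  norm <- centrality_table(rt$net, normalized = TRUE)$betweenness
  expect_equal(norm, raw / ((n - 1) * (n - 2) / 2))
  expect_true(all(norm >= 0 & norm <= 1))
})

test_that("top-k ranking is descending with deterministic tie-breaks", {
  tab <- data.frame(node_id = c("b", "a", "c", "d"),
                    node_type = "compound",
                    degree = c(5L, 5L, 9L, 5L),
                    betweenness = c(0.2, 0.2, 0.1, 0.5))
  top <- rank_top_k(tab, "degree", k = 4)
  # c wins on degree; d breaks the 5-tie on betweenness; a/b tie fully -> id
  expect_equal(top$node_id, c("c", "d", "a", "b"))
  expect_equal(nrow(rank_top_k(tab, "degree", k = 2)), 2L)
  empty <- tab[0, ]
  expect_equal(nrow(rank_top_k(empty, "degree", k = 3)), 0L)
})

test_that("overlap satisfies inclusion-exclusion and symmetry in both modes", {
  ov <- overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$size_intersection, ov$size_a + ov$size_b - ov$size_union)
  expect_equal(ov$members_intersection, c("b", "c"))
  ba <- overlap(c("b", "c", "d"), c("a", "b", "c"))
  expect_equal(ba$size_intersection, ov$size_intersection)
  same <- overlap(c("x", "y"), c("y", "x"))
  expect_equal(same$size_intersection, 2L)
  expect_equal(same$size_union, 2L)
  # size-only mode agrees with membership mode
  ov2 <- overlap(3, 3, universe_size = 4)
  expect_equal(ov2$size_intersection, ov$size_intersection)
  expect_error(overlap(3, 3, universe_size = 10), "inconsistent")
})

test_that("herb contribution counts shared compounds once per herb", {
  compound_herbs <- data.frame(
    compound_id = c("C1", "C2", "C3"),
    herbs = c("DG;CX", "DG", "CX"))
  hemo <- build_network(c("DG", "CX"), c("C1", "C2"), "T1",
                        data.frame(herb = c("DG", "CX", "DG"),
                                   compound = c("C1", "C1", "C2")),
                        data.frame(compound = c("C1", "C2"), target = c("T1", "T1")))
  coag <- build_network("CX", "C3", "T2",
                        data.frame(herb = "CX", compound = "C3"),
                        data.frame(compound = "C3", target = "T2"))
  hc <- herb_contribution(hemo, coag, compound_herbs)
  dg <- hc[hc$herb == "DG", ]
  cx <- hc[hc$herb == "CX", ]
  expect_equal(c(dg$total, dg$hemorheology, dg$coagulopathy), c(2L, 2L, 0L))
  expect_equal(c(cx$total, cx$hemorheology, cx$coagulopathy), c(2L, 1L, 1L))
  expect_true(all(hc$hemorheology <= hc$total & hc$coagulopathy <= hc$total))
})

test_that("network exports round-trip through SIF and GraphML", {
  rt <- random_tripartite(4)
  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  write_sif(rt$net, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(rt$net$edges))
  expect_true(all(grepl("\t(herb-compound|compound-target)\t", lines)))
  write_graphml(rt$net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(rt$net$nodes))
  expect_equal(igraph::ecount(g), nrow(rt$net$edges))
  expect_setequal(igraph::vertex_attr(g, "type"), unique(rt$net$nodes$type))
  unlink(c(sif, gml))
})
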
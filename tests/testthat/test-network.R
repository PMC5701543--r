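test_that("assembly anchors the PPI to the target node set", {
  assoc <- data.frame(compound_id = c("c1", "c1", "c1", "c2", "c2", "c2"),
                      target_symbol = rep(c("A", "B", "C"), 2))
  dis <- data.frame(disease_id = "T2D", target_symbol = c("C", "D"))
  ppi <- data.frame(from = c("A", "C", "D"), to = c("B", "D", "E"))
  net <- assemble_network(assoc, dis, ppi, quiet = TRUE)
  expect_setequal(net_nodes(net)$id, c("A", "B", "C", "D")) # E dropped
  expect_equal(nrow(net_edges(net)), 2)
  expect_setequal(paste(net_edges(net)$from, net_edges(net)$to),
                  c("A B", "C D"))
  # annotations
  nd <- net_nodes(net)
  expect_true(all(nd$putative[nd$id %in% c("A", "B", "C")]))
  expect_false(nd$putative[nd$id == "D"])
  expect_setequal(nd$id[nd$T2D], c("C", "D"))
})

test_that("assembly tolerates an empty PPI and counts dropped rows", {
  assoc <- data.frame(compound_id = "c1", target_symbol = c("A", "B"))
  net <- assemble_network(assoc, NULL, data.frame(from = character(),
                                                  to = character()),
                          quiet = TRUE)
  expect_equal(n_nodes(net), 2)
  expect_equal(n_edges(net), 0)

  ppi <- data.frame(from = c("A", "A", "B", "A"), to = c("B", "B", "A", "A"))
  net2 <- assemble_network(assoc, NULL, ppi, quiet = TRUE)
  expect_equal(n_edges(net2), 1) # dup rows, reversed dup, self-loop all gone
  expect_equal(attr(net2, "dropped_ppi"), 3)

  expect_error(assemble_network(assoc[0, ], NULL,
                                data.frame(from = "A", to = "B"),
                                quiet = TRUE),
               "No protein nodes")
})

test_that("source nodes attach for visualization with ct/dt relations", {
  assoc <- data.frame(compound_id = "c1", target_symbol = c("A", "B"))
  dis <- data.frame(disease_id = "HT", target_symbol = "B")
  ppi <- data.frame(from = "A", to = "B")
  net <- assemble_network(assoc, dis, ppi, include_source_nodes = TRUE,
                          quiet = TRUE)
  nd <- net_nodes(net)
  expect_setequal(nd$role, c("protein", "compound", "disease-source"))
  rel <- table(net_edges(net)$relation)
  expect_equal(as.integer(rel[c("ct", "dt", "pp")]), c(2L, 1L, 1L))
})

test_that("induced subgraphs keep exactly the requested nodes and edges", {
  tri <- make_net(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  sub <- induced_subgraph(tri, c("a", "b"))
  expect_equal(n_nodes(sub), 2)
  expect_equal(n_edges(sub), 1)
  # identity on the full node set
  expect_equal(induced_subgraph(tri, net_nodes(tri)$id), tri)
  # non-adjacent survivors become isolated
  path <- make_net(data.frame(from = c("a", "b"), to = c("b", "c")))
  sub2 <- induced_subgraph(path, c("a", "c"))
  expect_equal(n_nodes(sub2), 2)
  expect_equal(n_edges(sub2), 0)
  expect_error(induced_subgraph(tri, c("a", "nope")), "nope")
})

test_that("bipartite networks 2-colour by role and deduplicate pairs", {
  bp <- bipartite_network(data.frame(c("c1", "c1", "c2"), c("T1", "T2", "T1")))
  expect_equal(n_nodes(bp), 4)
  expect_equal(n_edges(bp), 3)
  deg <- node_degree(bp)
  expect_equal(deg$degree[deg$id == "T1"], 2)
  # every edge joins the two roles
  roles <- setNames(net_nodes(bp)$role, net_nodes(bp)$id)
  e <- net_edges(bp)
  expect_true(all(roles[e$from] != roles[e$to]))

  empty <- bipartite_network(data.frame(l = character(), r = character()))
  expect_equal(n_nodes(empty), 0)
  expect_error(bipartite_network(data.frame(l = "x", r = "x")), "equal")
})

test_that("bipartite role 2-colouring holds on random instances", {
  for (s in 1:10) {
    set.seed(s)
    pairs <- data.frame(left = sample(paste0("c", 1:5), 12, replace = TRUE),
                        right = sample(paste0("T", 1:6), 12, replace = TRUE))
    pairs <- pairs[!duplicated(pairs), ]
    bp <- bipartite_network(pairs)
    roles <- setNames(net_nodes(bp)$role, net_nodes(bp)$id)
    e <- net_edges(bp)
    expect_true(all(roles[e$from] != roles[e$to]))
    expect_equal(n_edges(bp), nrow(pairs))
  }
})

test_that("assembled edges never leave the node set (random inputs)", {
  for (s in 1:10) {
    set.seed(200 + s)
    genes <- sprintf("g%02d", 1:20)
    assoc <- data.frame(compound_id = sample(c("c1", "c2"), 10, TRUE),
                        target_symbol = sample(genes, 10))
    dis <- data.frame(disease_id = sample(c("D1", "D2"), 6, TRUE),
                      target_symbol = sample(genes, 6))
    ppi <- data.frame(from = sample(genes, 25, TRUE),
                      to = sample(genes, 25, TRUE))
    net <- suppressMessages(assemble_network(assoc, dis, ppi, quiet = TRUE))
    e <- net_edges(net)
    expect_true(all(c(e$from, e$to) %in% net_nodes(net)$id))
    expect_true(all(e$from < e$to)) # canonical, no self-loops
    expect_false(any(duplicated(paste(e$from, e$to))))
  }
})

test_that("constructor rejects malformed networks", {
  expect_error(interaction_network(data.frame(id = c("a", "a"), role = "p")),
               "Duplicate")
  expect_error(interaction_network(data.frame(id = "a", role = "p"),
                                   data.frame(from = "a", to = "a")),
               "Self-loops")
  expect_error(interaction_network(data.frame(id = "a", role = "p"),
                                   data.frame(from = "a", to = "b")),
               "absent")
})
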
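path3 <- make_net(data.frame(from = c("a", "b"), to = c("b", "c")))
k4 <- make_net(t(combn(c("a", "b", "c", "d"), 2)))
ring4 <- make_net(data.frame(from = c("a", "b", "c", "a"),
                             to = c("b", "c", "d", "d")))

test_that("degree counts incident edges, including isolated nodes", {
  expect_equal(node_degree(path3)$degree, c(1, 2, 1))
  expect_true(all(node_degree(k4)$degree == 3))
  iso <- interaction_network(data.frame(id = c("a", "b", "z"), role = "p"),
                             data.frame(from = "a", to = "b"))
  deg <- node_degree(iso)
  expect_equal(deg$degree[deg$id == "z"], 0)
})

test_that("betweenness matches hand-derived values on canonical graphs", {
  bt <- node_betweenness(path3)
  expect_equal(setNames(bt$betweenness, bt$id), c(a = 0, b = 1, c = 0))
  # star: the centre carries every one of the choose(5,2) leaf pairs
  star <- make_net(data.frame(from = "hub", to = paste0("l", 1:5)))
  bt <- node_betweenness(star)
  expect_equal(bt$betweenness[bt$id == "hub"], 10)
  expect_true(all(bt$betweenness[bt$id != "hub"] == 0))
  # 4-cycle: each antipodal pair splits its 2 shortest paths
  bt <- node_betweenness(ring4)
  expect_true(all(abs(bt$betweenness - 0.5) < 1e-12))
})

test_that("closeness is the inverse distance sum over reachable nodes", {
  cl <- node_closeness(k4)
  expect_true(all(abs(cl$closeness - 1 / 3) < 1e-12))
  cl <- node_closeness(path3)
  expect_equal(setNames(cl$closeness, cl$id),
               c(a = 1 / 3, b = 1 / 2, c = 1 / 3))
  # two disjoint edges: each node reaches one neighbour at distance 1
  two <- make_net(data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_true(all(node_closeness(two)$closeness == 1))
  # a node with no neighbours has closeness 0 by convention
  iso <- interaction_network(data.frame(id = c("a", "b", "z"), role = "p"),
                             data.frame(from = "a", to = "b"))
  cl <- node_closeness(iso)
  expect_equal(cl$closeness[cl$id == "z"], 0)
})

test_that("core numbers follow iterative peeling", {
  tri <- make_net(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  expect_true(all(node_coreness(tri)$kcore == 2))
  trip <- make_net(data.frame(from = c("a", "a", "b", "c"),
                              to = c("b", "c", "c", "p")))
  kc <- node_coreness(trip)
  expect_equal(setNames(kc$kcore, kc$id), c(a = 2, b = 2, c = 2, p = 1))
  edgeless <- interaction_network(data.frame(id = c("x", "y"), role = "p"))
  expect_true(all(node_coreness(edgeless)$kcore == 0))
})

test_that("feature_median interpolates for even n and rejects empty input", {
  expect_equal(feature_median(c(1, 2, 3)), 2)
  expect_equal(feature_median(c(1, 2, 3, 4)), 2.5)
  expect_equal(feature_median(5), 5)
  expect_error(feature_median(numeric()), "empty")
})

test_that("topology_profile bundles all four features with their medians", {
  prof <- topology_profile(ring4)
  expect_true(all(prof$degree == 2))
  expect_true(all(abs(prof$betweenness - 0.5) < 1e-12))
  expect_true(all(abs(prof$closeness - 0.25) < 1e-12))
  expect_true(all(prof$kcore == 2))
  expect_equal(attr(prof, "medians"),
               c(degree = 2, betweenness = 0.5, closeness = 0.25, kcore = 2))
  g <- glance(prof)
  expect_equal(g$median_closeness, 0.25)

  single <- make_net(data.frame(from = "a", to = "b"))
  prof <- topology_profile(single)
  expect_equal(prof$degree, c(1, 1))
  expect_equal(prof$betweenness, c(0, 0))
  expect_equal(prof$closeness, c(1, 1))
  expect_equal(prof$kcore, c(1, 1))
})

test_that("all three centralities agree with igraph on larger random graphs", {
  for (s in 1:12) {
    set.seed(300 + s)
    n <- sample(15:40, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.05, 0.3))
    el <- igraph::as_edgelist(g)
    ids <- sprintf("v%03d", seq_len(n))
    net <- interaction_network(data.frame(id = ids, role = "protein"),
                               if (nrow(el)) data.frame(from = ids[el[, 1]],
                                                        to = ids[el[, 2]])
                               else NULL)
    ord <- match(ids, node_degree(net)$id)
    expect_equal(node_betweenness(net)$betweenness[ord],
                 unname(igraph::betweenness(g)), tolerance = 1e-10)
    ig_cl <- suppressWarnings(igraph::closeness(g))
    ig_cl[igraph::degree(g) == 0] <- 0
    ig_cl[is.nan(ig_cl)] <- 0
    expect_equal(node_closeness(net)$closeness[ord], unname(ig_cl),
                 tolerance = 1e-10)
    expect_equal(node_coreness(net)$kcore[ord],
                 unname(igraph::coreness(g)))
  }
})

test_that("total betweenness cross-checks against brute force", {
  for (s in 1:5) {
    net <- random_er_net(n = 7, p = 0.4, seed = 400 + s)
    bt <- node_betweenness(net)
    brute <- brute_betweenness(net)
    expect_equal(sum(bt$betweenness), sum(brute), tolerance = 1e-9)
  }
})

test_that("core number is invariant under edge-order permutation", {
  edges <- data.frame(from = c("a", "a", "b", "c", "d", "d"),
                      to = c("b", "c", "c", "d", "e", "f"))
  base <- node_coreness(make_net(edges))
  for (s in 1:5) {
    set.seed(s)
    perm <- node_coreness(make_net(edges[sample(nrow(edges)), ]))
    expect_equal(perm[order(perm$id), ], base[order(base$id), ])
  }
})

test_that("adding an edge never decreases degree or core number", {
  for (s in 1:8) {
    net <- random_er_net(n = 8, p = 0.3, seed = 500 + s)
    ids <- net_nodes(net)$id
    e <- net_edges(net)
    present <- paste(e$from, e$to)
    pairs <- t(combn(ids, 2))
    free <- pairs[!paste(pairs[, 1], pairs[, 2]) %in% present, , drop = FALSE]
    if (!nrow(free)) next
    add <- free[1, ]
    net2 <- interaction_network(net_nodes(net),
                                rbind(e, data.frame(from = add[1], to = add[2],
                                                    relation = "pp")))
    d1 <- node_degree(net); d2 <- node_degree(net2)
    expect_true(all(d2$degree[match(d1$id, d2$id)] >= d1$degree))
    k1 <- node_coreness(net); k2 <- node_coreness(net2)
    expect_true(all(k2$kcore[match(k1$id, k2$id)] >= k1$kcore))
  }
})
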
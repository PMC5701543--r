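double_star <- function() {
  make_net(data.frame(
    from = c("u", rep("u", 5), rep("v", 5)),
    to = c("v", paste0("l", 1:5), paste0("m", 1:5))))
}

test_that("stage A deletes nodes below 2-fold the median degree", {
  res <- stage_a_filter(double_star())
  # degrees: hubs 6, leaves 1; median 1, threshold 2
  expect_equal(res$report$thresholds[["degree"]], 2)
  expect_setequal(res$report$retained, c("u", "v"))
  expect_equal(n_edges(res$network), 1)
  expect_equal(res$report$n_out, 2)
})

test_that("ties at exactly the threshold are kept", {
  # hubs u,v (degree 7), bridge w adjacent to both (degree 2 = threshold)
  net <- make_net(data.frame(
    from = c("u", rep("u", 5), rep("v", 5), "w", "w"),
    to = c("v", paste0("l", 1:5), paste0("m", 1:5), "u", "v")))
  res <- stage_a_filter(net)
  expect_equal(res$report$thresholds[["degree"]], 2)
  expect_true("w" %in% res$report$retained)
})

test_that("a regular graph empties at stage A with a warning, not an error", {
  ring6 <- make_net(data.frame(from = letters[1:6],
                               to = letters[c(2:6, 1)]))
  expect_warning(res <- stage_a_filter(ring6), "every node")
  expect_equal(n_nodes(res$network), 0)
  expect_true(res$report$emptied)
})

test_that("stage A is a contraction and respects the multiplier", {
  for (s in 1:8) {
    net <- random_er_net(n = 12, p = 0.3, seed = 600 + s)
    res <- suppressWarnings(stage_a_filter(net, multiplier = 1.5))
    expect_true(all(res$report$retained %in% net_nodes(net)$id))
    expect_equal(n_nodes(res$network), length(res$report$retained))
    deg <- node_degree(net)
    expect_setequal(res$report$retained,
                    deg$id[deg$degree >= res$report$thresholds[["degree"]]])
  }
  expect_error(stage_a_filter(double_star(), multiplier = -1), "positive")
})

test_that("stage B demands strict dominance of all four medians", {
  # 5-node toy: a-b, a-c, b-c, c-d, d-e; core median equals the maximum
  toy <- make_net(data.frame(from = c("a", "a", "b", "c", "d"),
                             to = c("b", "c", "c", "d", "e")))
  expect_warning(res <- stage_b_filter(toy), "no node")
  expect_length(res$key_targets, 0)
  # vertex-transitive graph: every feature ties at its median
  ring <- make_net(data.frame(from = letters[1:6], to = letters[c(2:6, 1)]))
  expect_warning(res <- stage_b_filter(ring), "no node")
  expect_length(res$key_targets, 0)
})

test_that("stage B retains strictly fewer than n nodes whenever n > 1", {
  for (s in 1:10) {
    net <- random_er_net(n = sample(4:10, 1), p = 0.5, seed = 700 + s)
    res <- suppressWarnings(stage_b_filter(net))
    expect_lt(length(res$key_targets), n_nodes(net))
  }
})

test_that("stage-B medians are recomputed on the stage-A hub network", {
  hn <- simulate_hub_network(seed = 3)
  net <- make_net(hn$edges, ids = sort(unique(c(hn$edges$from, hn$edges$to))))
  a <- stage_a_filter(net)
  b <- stage_b_filter(a$network)
  med_full <- attr(topology_profile(net), "medians")
  med_hub <- attr(topology_profile(a$network), "medians")
  expect_equal(b$report$medians, med_hub)
  expect_false(isTRUE(all.equal(med_hub, med_full)))
})

test_that("the two-stage filter recovers exactly the planted hubs", {
  for (s in c(11, 29, 73)) {
    hn <- simulate_hub_network(seed = s)
    net <- make_net(hn$edges, ids = sort(unique(c(hn$edges$from, hn$edges$to))))
    res <- key_target_pipeline(net)
    expect_identical(sort(res$key_targets), hn$hubs)
    expect_equal(n_nodes(res$key_network), length(hn$hubs))
  }
})

test_that("Venn partition decomposes sets into disjoint regions", {
  vp <- venn_partition(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(venn_region(vp, "A"), "1")
  expect_equal(venn_region(vp, "B"), "3")
  expect_equal(venn_region(vp, c("A", "B")), "2")
  expect_equal(venn_overlap(vp, c("A", "B")), 1)

  same <- venn_partition(list(X = c("a", "b"), Y = c("b", "a")))
  expect_equal(nrow(same), 1)
  expect_equal(same$region, "X&Y")

  expect_error(venn_partition(list(A = "x")), "at least 2")
  expect_error(venn_partition(setNames(list("x", "y"), c("A", "A"))),
               "unique")
})

test_that("Venn region counts always sum to the union size", {
  for (s in 1:10) {
    set.seed(800 + s)
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(i) {
      sample(sprintf("g%02d", 1:25), sample(3:15, 1))
    })
    names(sets) <- LETTERS[seq_len(k)]
    vp <- venn_partition(sets)
    expect_equal(sum(vp$count), length(unique(unlist(sets))))
    # regions are disjoint
    all_sym <- unlist(vp$symbols)
    expect_false(any(duplicated(all_sym)))
  }
})
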
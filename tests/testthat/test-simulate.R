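test_that("preferential-attachment PPI is deterministic and tree-like at m=1", {
  el <- simulate_ppi(3, attachment = 1, seed = 4)
  expect_equal(nrow(el), 2)
  expect_identical(simulate_ppi(50, 2, seed = 9), simulate_ppi(50, 2, seed = 9))
  expect_false(identical(simulate_ppi(50, 2, seed = 9),
                         simulate_ppi(50, 2, seed = 10)))
  expect_error(simulate_ppi(1), ">= 2")
})

test_that("large preferential-attachment graphs are heavy-tailed", {
  el <- simulate_ppi(10000, attachment = 2, seed = 5)
  deg <- table(c(el$from, el$to))
  expect_gte(max(deg), 20 * median(as.numeric(deg)))
})

test_that("overlap sets realise the planted region spec exactly", {
  spec <- c(A = 5, B = 3, C = 4, `A&B` = 2, `A&B&C` = 1)
  sim <- simulate_overlap_sets(spec, seed = 21)
  expect_equal(lengths(sim$sets), c(A = 8L, B = 6L, C = 5L))
  vp <- venn_partition(sim$sets)
  got <- setNames(vp$count, vapply(strsplit(vp$region, "&"),
                                   function(x) paste(sort(x), collapse = "&"), ""))
  want <- setNames(as.integer(spec), vapply(strsplit(names(spec), "&"),
                                            function(x) paste(sort(x), collapse = "&"), ""))
  expect_mapequal(as.list(got), as.list(want))

  disjoint <- simulate_overlap_sets(c(A = 3, B = 4), seed = 1)
  expect_length(intersect(disjoint$sets$A, disjoint$sets$B), 0)
  expect_identical(simulate_overlap_sets(spec, seed = 7),
                   simulate_overlap_sets(spec, seed = 7))
  expect_error(simulate_overlap_sets(c(A = -1)), "non-negative")
  expect_error(simulate_overlap_sets(c(3, 4)), "named")
})

test_that("planted pathway dominates ORA at fraction 1", {
  universe <- sprintf("G%06d", 1:1000)
  set.seed(31)
  query <- sample(universe, 10)
  pw <- simulate_pathways(universe, query, n_sets = 20, seed = 31)
  res <- run_ora(query, pw$collection)
  expect_equal(res$set_id[1], pw$planted_set_id)
  expect_lt(res$q_value[1], 1e-6)
})

test_that("a background-rate planted set is rarely significant", {
  universe <- sprintf("G%06d", 1:800)
  set.seed(77)
  query <- sample(universe, 7)
  hits <- 0L
  for (s in 1:200) {
    pw <- simulate_pathways(universe, query, n_sets = 20,
                            planted_fraction = 0.05, seed = 4000 + s)
    res <- run_ora(query, pw$collection, alpha = 0.05)
    if (pw$planted_set_id %in% res$set_id) hits <- hits + 1L
  }
  expect_lte(hits / 200, 0.05)
})

test_that("single-set collections contain exactly the planted set", {
  universe <- sprintf("G%06d", 1:100)
  pw <- simulate_pathways(universe, universe[1:10], n_sets = 1,
                          size_range = c(10, 10), seed = 3)
  expect_length(pw$collection, 1)
  expect_true(all(universe[1:10] %in% pw$collection[[1]]))
})

test_that("docking score generation is seeded and median-filter friendly", {
  pairs <- expand.grid(compound_id = sprintf("c%d", 1:5),
                       target_symbol = sprintf("T%d", 1:5),
                       stringsAsFactors = FALSE)[1:21, ]
  d1 <- simulate_docking_scores(pairs, seed = 8)
  expect_identical(d1, simulate_docking_scores(pairs, seed = 8))
  res <- filter_by_median(d1)
  expect_equal(nrow(res$retained), 10) # (21 - 1) / 2, scores distinct
  expect_error(simulate_docking_scores(pairs, sd = 0), "positive")
  expect_error(simulate_docking_scores(pairs[0, ]), "non-empty")
})

test_that("hub network has the designed three-tier structure", {
  hn <- simulate_hub_network(n_hubs = 6, n_mids = 8, n_pendants = 20, seed = 2)
  ids <- sort(unique(c(hn$edges$from, hn$edges$to)))
  expect_length(ids, 34)
  net <- make_net(hn$edges, ids = ids)
  deg <- node_degree(net)
  degv <- setNames(deg$degree, deg$id)
  expect_true(all(degv[hn$pendants] == 1))
  expect_true(all(degv[hn$hubs] >= 6 - 1 + 1)) # clique + >= 1 mid
  # mids: 2 cycle + 2 hubs + attached pendants
  expect_true(all(degv[hn$mids] >= 4))
  expect_error(simulate_hub_network(n_hubs = 3), ">= 6")
})

test_that("bundles are reproducible and internally consistent", {
  b1 <- simulate_bundle(seed = 5)
  b2 <- simulate_bundle(seed = 5)
  expect_identical(b1, b2)
  gt <- b1$ground_truth
  # ground-truth symbols exist in the generated tables
  expect_true(all(gt$hubs %in% c(b1$ppi$from, b1$ppi$to)))
  expect_true(all(unlist(gt$regions$symbols) %in%
                    c(b1$associations$target_symbol,
                      normalize_symbol(b1$disease_targets$target_symbol))))
  expect_true(gt$planted_pathway %in% names(b1$pathways))
  # every compound has at least one putative target
  expect_setequal(unique(b1$associations$compound_id), b1$compounds$compound_id)
})

test_that("written bundles pass every reader and are byte-stable per seed", {
  d1 <- file.path(tempdir(), "bndl_a")
  d2 <- file.path(tempdir(), "bndl_b")
  write_bundle(simulate_bundle(seed = 11), d1)
  write_bundle(simulate_bundle(seed = 11), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  expect_no_warning({
    read_compound_table(file.path(d1, "compounds.tsv"))
    read_target_associations(file.path(d1, "associations.tsv"), quiet = TRUE)
    read_disease_targets(file.path(d1, "disease_targets.tsv"))
    read_gmt(file.path(d1, "pathways.gmt"))
    read_docking_table(file.path(d1, "docking.tsv"), quiet = TRUE)
  })
})
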
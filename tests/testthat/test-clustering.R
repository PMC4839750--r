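two_triangles <- tibble::tibble(
  protein_a = c("A", "B", "A", "X", "Y", "X"),
  protein_b = c("B", "C", "C", "Y", "Z", "Z"))

test_that("MCL recovers disjoint triangles across a range of inflations", {
  for (r in c(1.5, 2, 2.5)) {
    cls <- mcl_cluster(two_triangles, mcl_params(inflation = r))
    expect_equal(cluster_set(cls), c("A B C", "X Y Z"))
  }
})

test_that("MCL handles trivial snapshots", {
  expect_equal(mcl_cluster(tibble::tibble(protein_a = "A", protein_b = "B")),
               list(c("A", "B")))
  expect_equal(mcl_cluster(tibble::tibble(protein_a = character(),
                                          protein_b = character())), list())
  expect_error(mcl_cluster(tibble::tibble(protein_a = "A", protein_b = "B",
                                          weight = -1)), "negative")
})

test_that("the MCL limit matrix matches a literal-transcription oracle", {
  set.seed(91)
  for (rep in 1:6) {
    e <- random_edges(sample(6:14, 1), 0.4, weighted = rep %% 2 == 0)
    if (nrow(e) == 0) next
    got <- tepinkit:::mcl_limit(local({
      nodes <- sort(unique(c(e$protein_a, e$protein_b)))
      a <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
      w <- if ("weight" %in% names(e)) e$weight else rep(1, nrow(e))
      a[cbind(match(e$protein_a, nodes), match(e$protein_b, nodes))] <- w
      a[cbind(match(e$protein_b, nodes), match(e$protein_a, nodes))] <- w
      diag(a) <- 1
      a
    }), mcl_params())
    want <- naive_mcl_limit(e)
    expect_equal(unclass(got), want, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("column sums stay stochastic throughout the iteration", {
  set.seed(92)
  for (rep in 1:5) {
    e <- random_edges(12, 0.35)
    if (nrow(e) == 0) next
    cls <- mcl_cluster(e)
    nodes <- sort(unique(c(e$protein_a, e$protein_b)))
    a <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    a[cbind(match(e$protein_a, nodes), match(e$protein_b, nodes))] <- 1
    a[cbind(match(e$protein_b, nodes), match(e$protein_a, nodes))] <- 1
    diag(a) <- 1
    m <- tepinkit:::mcl_limit(a, mcl_params())
    expect_lt(attr(m, "max_colsum_dev"), 1e-9)
    # every node assigned to >= 1 cluster
    expect_setequal(unique(unlist(cls)), nodes)
  }
})

test_that("MCL never merges nodes from different connected components", {
  skip_if_not_installed("igraph")
  set.seed(93)
  for (rep in 1:8) {
    e <- random_edges(16, 0.12)
    if (nrow(e) == 0) next
    g <- igraph::graph_from_data_frame(e, directed = FALSE)
    comp <- igraph::components(g)$membership
    for (cl in mcl_cluster(e)) {
      expect_equal(length(unique(comp[cl])), 1)
    }
  }
})

test_that("a clique with a pendant vertex reproduces the recorded reference run", {
  k5 <- t(utils::combn(sprintf("K%d", 1:5), 2))
  e <- tibble::tibble(protein_a = c(k5[, 1], "K1"),
                      protein_b = c(k5[, 2], "pend"))
  cls <- mcl_cluster(e, mcl_params(inflation = 2))
  # recorded oracle: at inflation 2 the pendant is absorbed into the clique
  expect_equal(cluster_set(cls), "K1 K2 K3 K4 K5 pend")
})

test_that("redundancy filtering follows the size-ordered overlap rule", {
  dup <- complex_catalog(list(a = c("A", "B", "C"), b = c("A", "B", "C")))
  expect_equal(nrow(filter_redundant(dup, 1)), 1)

  pair <- complex_catalog(list(big = c("A", "B", "C", "D"),
                               small = c("A", "B", "C")))  # OS = 9/12 = 0.75
  expect_equal(nrow(filter_redundant(pair, 0.8)), 2)
  kept <- filter_redundant(pair, 0.7)
  expect_equal(kept$complex, "big")  # smaller of the pair discarded

  os_ex <- complex_catalog(list(u = c("A", "B", "C"), o = c("A", "B")))
  expect_equal(overlap_score(os_ex$members[[1]], os_ex$members[[2]]), 4 / 6)
  expect_equal(nrow(filter_redundant(os_ex, 0.8)), 2)
})

test_that("redundancy filtering is idempotent, shrinking, and keeps the largest", {
  set.seed(94)
  for (rep in 1:10) {
    catalog <- random_catalog(15, sprintf("Y%02d", 1:25), c(2, 8))
    thr <- sample(c(0.4, 0.7, 1), 1)
    once <- filter_redundant(catalog, thr)
    twice <- filter_redundant(once, thr)
    expect_identical(once, twice)
    expect_lte(nrow(once), nrow(catalog))
    expect_true(max(catalog$size) %in% once$size)
    # no retained pair is redundant
    if (nrow(once) > 1) {
      for (i in 1:(nrow(once) - 1)) {
        for (j in (i + 1):nrow(once)) {
          expect_lt(overlap_score(once$members[[i]], once$members[[j]]), thr)
        }
      }
    }
  }
})

test_that("temporal mining merges snapshots, dedups, and records provenance", {
  pin <- as_pin(two_triangles)
  sched <- tibble::tibble(gene = pin_proteins(pin), mean = 0, sd = 0,
                          threshold = 0, n_active = 3,
                          active = rep(list(1:3), 6))
  attr(sched, "n_timepoints") <- 3L
  net <- build_tepin(pin, sched)
  pred <- mine_temporal_complexes(net, mcl_cluster, similarity_threshold = 1)
  expect_equal(cluster_set(pred$members), c("A B C", "X Y Z"))
  expect_equal(pred$timepoints, list(1:3, 1:3))  # same clusters at all 3 points

  empty_net <- build_tepin(pin, local({
    s <- sched[0, ]
    attr(s, "n_timepoints") <- 3L
    s
  }))
  expect_equal(nrow(mine_temporal_complexes(empty_net)), 0)
})

test_that("singleton clusters never reach the predicted catalogue", {
  # pendant-free star: MCL at high inflation splits leaves from the hub
  e <- tibble::tibble(protein_a = rep("H", 4), protein_b = sprintf("L%d", 1:4))
  net <- as_static_network(as_pin(e))
  pred <- mine_temporal_complexes(net, mcl_cluster,
                                  params = mcl_params(inflation = 10))
  expect_true(all(pred$size >= 2))
})
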
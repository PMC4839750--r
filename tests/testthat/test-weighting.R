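test_that("connected affinity follows N_k/R_k summed over containing complexes", {
  pin <- as_pin(tibble::tibble(protein_a = c("A", "B", "C"),
                               protein_b = c("B", "C", "D")))
  cat1 <- complex_catalog(list(k1 = c("A", "B", "C")))
  ca <- connected_affinity(pin, cat1)  # N=3, R=2 -> CC=1.5 on A-B and B-C
  expect_equal(ca$cac[ca$protein_a == "A" & ca$protein_b == "B"], 1.5)
  expect_equal(ca$cac[ca$protein_a == "B" & ca$protein_b == "C"], 1.5)
  expect_equal(ca$cac[ca$protein_a == "C" & ca$protein_b == "D"], 0)

  # an edge in two complexes accumulates both contributions
  cat2 <- complex_catalog(list(k1 = c("A", "B", "C"),
                               k2 = c("A", "B", "C", "D")))
  # k2: N=4, R=3 -> 4/3; A-B gets 1.5 + 4/3
  ca2 <- connected_affinity(pin, cat2)
  expect_equal(ca2$cac[ca2$protein_a == "A" & ca2$protein_b == "B"], 1.5 + 4 / 3)

  expect_true(all(connected_affinity(pin, complex_catalog(list()))$cac == 0))

  # complex inducing no PIN edge contributes nothing, with a log message
  cat3 <- complex_catalog(list(k1 = c("A", "B", "C"), off = c("X", "Y")))
  expect_message(ca3 <- connected_affinity(pin, cat3), "skipped")
  expect_equal(ca3$cac, ca$cac)
})

test_that("connected affinity equals brute-force enumeration on random instances", {
  set.seed(77)
  for (rep in 1:5) {
    pin <- as_pin(random_edges(sample(20:40, 1), 0.15))
    catalog <- random_catalog(sample(10:25, 1), pin_proteins(pin))
    got <- suppressMessages(connected_affinity(pin, catalog))$cac
    expect_equal(got, naive_cac(pin, catalog), tolerance = 1e-9)
  }
})

test_that("removing a complex never increases any edge's affinity", {
  set.seed(78)
  pin <- as_pin(random_edges(25, 0.2))
  catalog <- random_catalog(15, pin_proteins(pin))
  full <- suppressMessages(connected_affinity(pin, catalog))$cac
  for (drop in sample(nrow(catalog), 5)) {
    less <- suppressMessages(connected_affinity(pin, catalog[-drop, ]))$cac
    expect_true(all(less <= full + 1e-12))
  }
})

test_that("pearson_cc matches hand-evaluated values and handles degeneracy", {
  expect_equal(pearson_cc(1:5, 1:5 * 2), 1)
  expect_equal(pearson_cc(1:5, -(1:5)), -1)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 4)), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-9)  # 0.98198...
  expect_equal(pearson_cc(c(2, 2, 2), c(1, 5, 3)), 0)  # zero variance -> 0
  expect_error(pearson_cc(1:3, 1:4), "mismatch")
})

test_that("pearson_cc is invariant under positive affine transforms", {
  set.seed(79)
  for (i in 1:50) {
    x <- rnorm(10)
    y <- rnorm(10)
    a <- runif(2, 0.1, 10)
    b <- runif(2, -20, 20)
    expect_equal(pearson_cc(a[1] * x + b[1], a[2] * y + b[2]),
                 pearson_cc(x, y), tolerance = 1e-9)
  }
})

test_that("weighting combines CAC and PCC and drops non-positive edges", {
  pin <- as_pin(tibble::tibble(protein_a = c("A", "C"), protein_b = c("B", "D")))
  # A,B co-member of a complex and anti-correlated; C,D only anti-correlated
  expr <- tibble::tibble(gene = c("A", "B", "C", "D"),
                         T1 = c(1, 3, 1, 3), T2 = c(2, 2, 2, 2.5),
                         T3 = c(3, 1, 3, 1), T4 = c(2, 2, 2, 2))
  catalog <- complex_catalog(list(k = c("A", "B")))
  sched <- activity_profiles(expr, detect_global_threshold(-Inf))
  net <- build_tepin(pin, sched)
  wnet <- suppressMessages(weight_network(net, pin, expr, catalog))
  e1 <- snapshot_edges(wnet, 1)
  # A-B: CAC = 2/1 = 2, PCC < 0 but W > 0 -> kept; C-D: CAC 0, PCC < 0 -> dropped
  expect_equal(nrow(e1), 1)
  expect_equal(e1$protein_a, "A")
  pcc_ab <- pearson_cc(c(1, 2, 3, 2), c(3, 2, 1, 2))
  expect_equal(e1$weight, 2 + pcc_ab, tolerance = 1e-9)
  elim <- elimination_ratios(wnet)
  expect_equal(elim$ratio, rep(0.5, 4))
})

test_that("edges lacking expression fall back to the affinity term alone", {
  pin <- as_pin(tibble::tibble(protein_a = "A", protein_b = "B"))
  expr <- tibble::tibble(gene = "A", T1 = 1, T2 = 5, T3 = 2)
  catalog <- complex_catalog(list(k = c("A", "B")))
  net <- as_static_network(pin)
  expect_message(wnet <- weight_network(net, pin, expr, catalog),
                 "lack expression")
  expect_equal(snapshot_edges(wnet, 1)$weight, 2)  # CAC only
})

test_that("weighted snapshots are edge-subsets of the unweighted network", {
  d <- generate_synthetic(synth_config(n_proteins = 80, n_complexes = 6, seed = 4))
  net <- build_tepin(d$pin, activity_profiles(d$expr))
  wnet <- suppressMessages(weight_network(net, d$pin, d$expr, d$known))
  k0 <- with(net$edges, paste(timepoint, protein_a, protein_b))
  kw <- with(wnet$edges, paste(timepoint, protein_a, protein_b))
  expect_true(all(kw %in% k0))
  expect_true(all(wnet$edges$weight > 0))
  # elimination stays in a plausible band on the default-style configuration
  r <- elimination_ratios(wnet)$ratio
  expect_true(mean(r) > 0.005 && mean(r) < 0.6)
})
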
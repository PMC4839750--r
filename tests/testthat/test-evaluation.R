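test_that("overlap score matches its defining formula", {
  s5 <- sprintf("P%d", 1:5)
  expect_equal(overlap_score(s5, s5), 1)
  expect_equal(overlap_score(c("A", "B"), c("C", "D")), 0)
  expect_equal(overlap_score(c("A", "B", "X", "Y"), c("A", "B", "p", "q", "r")),
               4 / 20)  # |pc|=4, |kc|=5, overlap 2
  expect_error(overlap_score(character(0), "A"), "empty")
})

test_that("overlap score is symmetric and bounded by the size ratio", {
  set.seed(111)
  pool <- sprintf("Y%02d", 1:30)
  for (i in 1:100) {
    a <- sample(pool, sample(1:10, 1))
    b <- sample(pool, sample(1:10, 1))
    os <- overlap_score(a, b)
    expect_equal(os, overlap_score(b, a))
    expect_gte(os, 0)
    expect_lte(os, min(length(a), length(b)) / max(length(a), length(b)) + 1e-12)
  }
})

test_that("matching handles the degenerate catalogues exactly", {
  cat1 <- random_catalog(8, sprintf("Y%02d", 1:40))
  m_self <- match_complexes(cat1, cat1, 0.2)
  expect_equal(m_self$tp, 8)
  expect_equal(m_self$fp, 0)
  expect_equal(m_self$fn, 0)
  expect_equal(m_self$perfect, 8)

  cat2 <- random_catalog(5, sprintf("Z%02d", 1:30))
  m_disj <- match_complexes(cat1, cat2, 0.2)
  expect_equal(m_disj$tp, 0)
  expect_equal(m_disj$mkc, 0)
})

test_that("matching agrees with an all-pairs brute-force oracle", {
  set.seed(112)
  for (rep in 1:5) {
    pool <- sprintf("Y%02d", 1:35)
    pred <- random_catalog(sample(5:25, 1), pool)
    known <- random_catalog(sample(5:25, 1), pool)
    names(known$complex) <- NULL
    thr <- sample(c(0.2, 0.4, 0.8), 1)
    got <- match_complexes(pred, known, thr)
    want <- naive_match(pred, known, thr)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$mkc, want$mkc)
    expect_equal(got$fn, want$fn)
    expect_equal(got$perfect, want$perfect)
    # conservation invariants
    expect_equal(got$tp + got$fp, nrow(pred))
    expect_equal(got$mkc + got$fn, nrow(known))
  }
})

test_that("raising the match threshold never increases TP or MKC", {
  set.seed(113)
  pool <- sprintf("Y%02d", 1:30)
  pred <- random_catalog(15, pool)
  known <- random_catalog(15, pool)
  ms <- lapply(c(0.2, 0.4, 0.6, 0.8, 1), function(t) match_complexes(pred, known, t))
  tp <- vapply(ms, `[[`, numeric(1), "tp")
  mkc <- vapply(ms, `[[`, numeric(1), "mkc")
  expect_true(all(diff(tp) <= 0))
  expect_true(all(diff(mkc) <= 0))
})

test_that("accuracy metrics follow the Sn/Sp/F definitions with safe zeros", {
  m <- match_result(tp = 6, fp = 2, fn = 3, mkc = 5)
  a <- accuracy_metrics(m)
  expect_equal(a$sn, 6 / 9)
  expect_equal(a$sp, 6 / 8)
  expect_equal(a$f_measure, 2 * (6 / 9) * (6 / 8) / (6 / 9 + 6 / 8))
  expect_true(a$f_measure >= min(a$sn, a$sp) &&
                a$f_measure <= 2 * min(a$sn, a$sp))

  z <- suppressWarnings(accuracy_metrics(match_result(tp = 0, fp = 0, fn = 0)))
  expect_equal(c(z$sn, z$sp, z$f_measure), c(0, 0, 0))
})

test_that("enrichment p-values are exact hypergeometric upper tails", {
  expect_equal(enrichment_pvalue(0, 5, 10, 100), 1)
  expect_equal(enrichment_pvalue(2, 2, 5, 10), 10 / 45, tolerance = 1e-12)
  expect_error(enrichment_pvalue(3, 2, 5, 10), "require")
  expect_error(enrichment_pvalue(1, 2, 11, 10), "require")

  set.seed(114)
  for (i in 1:500) {
    N <- sample(20:2000, 1)
    F_ <- sample(1:N, 1)
    C <- sample(1:min(60, N), 1)
    k <- sample(0:min(C, F_), 1)
    expect_equal(enrichment_pvalue(k, C, F_, N), phyper_upper(k, C, F_, N),
                 tolerance = 1e-9)
  }
})

test_that("log-space evaluation keeps extreme p-values exact", {
  # fully contained large complex in a small class: far below double-precision
  # reach of 1 - cdf
  p <- enrichment_pvalue(20, 20, 25, 6000)
  expect_lt(p, 1e-40)
  expect_equal(log(p), log(phyper_upper(20, 20, 25, 6000)), tolerance = 1e-6)
})

test_that("complex annotation picks the best term and bins p-values", {
  ann <- tibble::tibble(term = c("t1", "t2"),
                        members = list(sprintf("A%d", 1:6), sprintf("B%d", 1:40)),
                        size = c(6L, 40L))
  attr(ann, "genome_size") <- 2000L
  pred <- complex_catalog(list(inside = sprintf("A%d", 1:5),
                               dark = c("Q1", "Q2", "Q3")))
  res <- annotate_complexes(pred, ann)
  ins <- res[res$complex == "inside", ]
  expect_equal(ins$term, "t1")
  expect_lt(ins$p_value, 1e-10)
  expect_true(ins$significant)
  drk <- res[res$complex == "dark", ]
  expect_equal(drk$p_value, 1)  # unannotated members
  expect_false(drk$significant)
  expect_equal(as.character(drk$bin), ">=0.01")

  bins <- enrichment_bins(res)
  expect_equal(sum(bins$n), nrow(res))
})

test_that("matched-known percentage validates its inputs", {
  expect_equal(matched_known_percentage(0, 50), 0)
  expect_error(matched_known_percentage(5, 0), "positive")
  expect_error(matched_known_percentage(5, 3), "smaller")
  m <- match_complexes(random_catalog(4, sprintf("Y%d", 1:20)),
                       random_catalog(4, sprintf("Y%d", 1:20)), 0.2)
  expect_equal(matched_known_percentage(m), 100 * m$mkc / 4)
})
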
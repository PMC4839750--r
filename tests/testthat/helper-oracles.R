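# Independent brute-force oracles, written as literal transcriptions of the
# defining formulas with explicit loops.  They deliberately share no code
# with the package implementation.

# mean / sample-sd / threshold / strict-exceedance active set, element by
# element
naive_deviation <- function(x) {
  n <- length(x)
  u <- 0
  for (v in x) u <- u + v
  u <- u / n
  ss <- 0
  for (v in x) ss <- ss + (v - u)^2
  sigma <- sqrt(ss / (n - 1))
  thr <- u + sigma
  act <- integer(0)
  for (t in seq_len(n)) if (x[t] > thr) act <- c(act, t)
  list(mean = u, sd = sigma, threshold = thr, active = act)
}

# per-edge connected affinity by full enumeration: for every edge, scan every
# complex, recompute member and induced-interaction counts from scratch
naive_cac <- function(pin, catalog) {
  has_edge <- function(a, b) {
    any((pin$protein_a == a & pin$protein_b == b) |
          (pin$protein_a == b & pin$protein_b == a))
  }
  out <- numeric(nrow(pin))
  for (e in seq_len(nrow(pin))) {
    a <- pin$protein_a[e]
    b <- pin$protein_b[e]
    total <- 0
    for (k in seq_len(nrow(catalog))) {
      mem <- catalog$members[[k]]
      if (!(a %in% mem) || !(b %in% mem)) next
      nk <- length(mem)
      rk <- 0
      for (i in seq_along(mem)) {
        for (j in seq_along(mem)) {
          if (i < j && has_edge(mem[i], mem[j])) rk <- rk + 1
        }
      }
      if (rk > 0) total <- total + nk / rk
    }
    out[e] <- total
  }
  out
}

# all-pairs overlap-score matching with explicit counting
naive_match <- function(predicted, known, threshold) {
  os <- function(p, k) length(intersect(p, k))^2 / (length(p) * length(k))
  tp <- 0
  for (i in seq_len(nrow(predicted))) {
    hit <- FALSE
    for (j in seq_len(nrow(known))) {
      if (os(predicted$members[[i]], known$members[[j]]) >= threshold) hit <- TRUE
    }
    if (hit) tp <- tp + 1
  }
  mkc <- 0
  perfect <- 0
  for (j in seq_len(nrow(known))) {
    hit <- FALSE
    perf <- FALSE
    for (i in seq_len(nrow(predicted))) {
      o <- os(predicted$members[[i]], known$members[[j]])
      if (o >= threshold) hit <- TRUE
      if (o == 1) perf <- TRUE
    }
    if (hit) mkc <- mkc + 1
    if (perf) perfect <- perfect + 1
  }
  list(tp = tp, fp = nrow(predicted) - tp, mkc = mkc,
       fn = nrow(known) - mkc, perfect = perfect)
}

# literal Markov-clustering limit matrix: column normalisation, squaring,
# entrywise inflation, pruning — all with explicit column loops
naive_mcl_limit <- function(edges, inflation = 2, self_loop = 1,
                            prune = 1e-5, max_iter = 100, tol = 1e-6) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$protein_a[r], nodes)
    j <- match(edges$protein_b[r], nodes)
    w <- if ("weight" %in% names(edges)) edges$weight[r] else 1
    A[i, j] <- w
    A[j, i] <- w
  }
  for (i in seq_len(n)) A[i, i] <- self_loop
  norm_cols <- function(M) {
    for (j in seq_len(n)) {
      s <- sum(M[, j])
      if (s == 0) {
        M[j, j] <- 1
        s <- 1
      }
      M[, j] <- M[, j] / s
    }
    M
  }
  M <- norm_cols(A)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- norm_cols(M2)
    M2[M2 < prune] <- 0
    M2 <- norm_cols(M2)
    d <- max(abs(M2 - M))
    M <- M2
    if (d < tol) break
  }
  M
}

# hypergeometric upper-tail oracle via the distribution function
phyper_upper <- function(k, C, F_, N) {
  stats::phyper(k - 1, F_, N - F_, C, lower.tail = FALSE)
}

# random small graphs / catalogs for property tests
random_edges <- function(n_nodes, p, weighted = FALSE) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  e <- tibble::tibble(protein_a = pairs[1, keep], protein_b = pairs[2, keep])
  if (weighted) e$weight <- stats::runif(nrow(e), 0.2, 2)
  e
}

random_catalog <- function(n_complexes, pool, size_range = c(2, 6)) {
  sets <- lapply(seq_len(n_complexes), function(i) {
    sample(pool, sample(size_range[1]:size_range[2], 1))
  })
  names(sets) <- sprintf("R%03d", seq_len(n_complexes))
  complex_catalog(sets)
}

cluster_set <- function(clusters) {
  sort(vapply(clusters, function(cl) paste(sort(cl), collapse = " "), character(1)))
}
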
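# Markov clustering of snapshots and assembly of the temporal complex set:
# cluster every snapshot, merge the n result groups, drop singletons, and
# filter redundant complexes by overlap score in descending size order.

#' Markov clustering parameters
#'
#' Community-standard defaults: inflation 2.0, unit self-loops, pruning of
#' matrix entries below 1e-5, at most 100 expansion/inflation rounds, and a
#' convergence tolerance of 1e-6 on the max entrywise change.
#'
#' @param inflation Inflation exponent (> 1); larger values give finer
#'   clusters.
#' @param self_loop_weight Weight added on the diagonal before normalising
#'   (>= 0); self-loops damp oscillations.
#' @param prune_threshold Entries below this are zeroed after each round
#'   (>= 0).
#' @param max_iterations Iteration cap (positive integer).
#' @param convergence_tol Convergence tolerance (> 0).
#' @return A list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2, self_loop_weight = 1,
                       prune_threshold = 1e-5, max_iterations = 100,
                       convergence_tol = 1e-6) {
  stopifnot(inflation > 1, self_loop_weight >= 0, prune_threshold >= 0,
            max_iterations >= 1, convergence_tol > 0)
  structure(list(inflation = inflation, self_loop_weight = self_loop_weight,
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "mcl_params")
}

# column-normalise, zero-guarding empty columns by dropping them to the
# diagonal (cannot arise for nodes that carry at least one edge plus a
# self-loop, but keeps the iteration well defined)
mcl_normalize <- function(m) {
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    m[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(m, 2, cs, "/")
}

# iterate expansion (matrix square) and inflation (entrywise power +
# renormalise) with pruning until the matrix stabilises; returns the limit
# matrix with iteration diagnostics attached
mcl_limit <- function(adj, params = mcl_params()) {
  m <- mcl_normalize(adj)
  max_colsum_dev <- 0
  iters <- 0L
  for (it in seq_len(params$max_iterations)) {
    iters <- it
    m2 <- m %*% m
    m2 <- m2^params$inflation
    m2 <- mcl_normalize(m2)
    m2[m2 < params$prune_threshold] <- 0
    m2 <- mcl_normalize(m2)
    max_colsum_dev <- max(max_colsum_dev, max(abs(colSums(m2) - 1)))
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < params$convergence_tol) break
  }
  attr(m, "iterations") <- iters
  attr(m, "max_colsum_dev") <- max_colsum_dev
  m
}

# read clusters off the limit matrix: attractors are nodes with positive
# diagonal; attractor systems (attractors that flow into each other) are
# merged, and each system's cluster is the set of nodes with positive flow
# into any of its attractor rows.  A node supported by two systems joins
# both clusters (overlap is allowed); unassigned nodes become singletons.
mcl_read_clusters <- function(m, nodes) {
  n <- length(nodes)
  attractors <- which(diag(m) > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)
  parent <- seq_along(attractors)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (ai in seq_along(attractors)) {
    for (bi in seq_along(attractors)) {
      if (ai < bi) {
        a <- attractors[ai]
        b <- attractors[bi]
        if (m[a, b] > 0 || m[b, a] > 0) {
          ra <- find(ai)
          rb <- find(bi)
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
  }
  roots <- vapply(seq_along(attractors), find, integer(1))
  clusters <- lapply(unique(roots), function(r) {
    rows <- attractors[roots == r]
    support <- which(colSums(m[rows, , drop = FALSE]) > 0)
    sort(nodes[unique(c(rows, support))])
  })
  covered <- unique(unlist(lapply(clusters, function(cl) match(cl, nodes))))
  lonely <- setdiff(seq_len(n), covered)
  clusters <- c(clusters, lapply(lonely, function(i) nodes[i]))
  clusters <- unique(clusters)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(cl) paste(cl, collapse = " "), character(1)))
  clusters[ord]
}

#' Markov clustering of a snapshot edge list
#'
#' Builds the symmetric weighted adjacency matrix with self-loops, column
#' normalises, and alternates expansion (matrix squaring) and inflation
#' (entrywise power then renormalisation) with pruning of small entries
#' until convergence.  Clusters are read off attractor rows; every node in
#' the edge list is assigned to at least one cluster, and the procedure is
#' deterministic (nodes are processed in sorted order).
#'
#' @param edges Edge tibble with columns `protein_a`, `protein_b` and an
#'   optional non-negative `weight` (unit weights otherwise).
#' @param params [mcl_params()].
#' @return List of character vectors (clusters), sorted by decreasing size.
#' @examples
#' tri2 <- tibble::tibble(protein_a = c("A", "B", "A", "X", "Y", "X"),
#'                        protein_b = c("B", "C", "C", "Y", "Z", "Z"))
#' mcl_cluster(tri2)
#' @export
mcl_cluster <- function(edges, params = mcl_params()) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  w <- edges[["weight"]] %||% rep(1, nrow(edges))
  if (any(w < 0)) stop("negative edge weight passed to MCL", call. = FALSE)
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  adj[cbind(ia, ib)] <- w
  adj[cbind(ib, ia)] <- w
  diag(adj) <- params$self_loop_weight
  m <- mcl_limit(adj, params)
  mcl_read_clusters(m, nodes)
}

member_key <- function(members) paste(sort(members), collapse = "\r")

#' Mine temporal protein complexes from a network
#'
#' Runs a clustering algorithm separately on each snapshot, merges the n
#' result groups into one, removes single-protein clusters, and applies the
#' size-ordered redundancy filter ([filter_redundant()]).  Identical member
#' sets arising at several time points are kept once, with all contributing
#' time points recorded as provenance.
#'
#' @param net A `tepin` (weighted or not).
#' @param clusterer Function mapping a snapshot edge tibble to a list of
#'   protein-ID vectors; default [mcl_cluster]. Any external algorithm with
#'   that signature can be plugged in.
#' @param similarity_threshold Redundancy threshold in (0, 1]; default 1.0
#'   (drop exact-overlap duplicates only).
#' @param ... Passed on to `clusterer`.
#' @return Predicted-complex catalogue: tibble with columns `complex`,
#'   `members`, `size`, and `timepoints` (list of source time points).
#' @export
mine_temporal_complexes <- function(net, clusterer = mcl_cluster,
                                    similarity_threshold = 1, ...) {
  stopifnot(inherits(net, "tepin"))
  found <- list()  # key -> list(members, timepoints)
  for (t in seq_len(net$n_timepoints)) {
    cls <- clusterer(snapshot_edges(net, t), ...)
    for (cl in cls) {
      if (length(cl) < 2) next
      k <- member_key(cl)
      if (is.null(found[[k]])) {
        found[[k]] <- list(members = sort(cl), timepoints = t)
      } else {
        found[[k]]$timepoints <- c(found[[k]]$timepoints, t)
      }
    }
  }
  if (length(found) == 0) {
    return(tibble::tibble(complex = character(), members = list(),
                          size = integer(), timepoints = list()))
  }
  found <- found[order(names(found))]
  cat <- tibble::tibble(
    complex = sprintf("TC%04d", seq_along(found)),
    members = unname(lapply(found, `[[`, "members")),
    size = unname(vapply(found, function(x) length(x$members), integer(1))),
    timepoints = unname(lapply(found, function(x) as.integer(unique(x$timepoints))))
  )
  filter_redundant(cat, similarity_threshold)
}

#' Filter redundant complexes by overlap score
#'
#' Complexes are sorted by decreasing size (ties broken lexicographically on
#' the sorted member list, for determinism).  Scanning down the order, each
#' retained complex discards every later (smaller-or-equal) complex whose
#' overlap score with it reaches the threshold.  The largest complex is
#' never discarded and the operation is idempotent.
#'
#' @param catalog Predicted-complex catalogue tibble.
#' @param similarity_threshold Overlap-score threshold in (0, 1]; a pair
#'   with OS >= this value is considered redundant.  At 1.0 only
#'   exact-overlap duplicates are dropped.
#' @return The filtered catalogue, in descending-size order.
#' @export
filter_redundant <- function(catalog, similarity_threshold = 1) {
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1)
  m <- nrow(catalog)
  if (m == 0) return(catalog)
  keys <- vapply(catalog$members, member_key, character(1))
  ord <- order(-catalog$size, keys)
  cat <- catalog[ord, , drop = FALSE]
  keep <- rep(TRUE, m)
  for (u in seq_len(m - 1)) {
    if (!keep[u]) next
    for (o in (u + 1):m) {
      if (!keep[o]) next
      if (overlap_score(cat$members[[u]], cat$members[[o]]) >= similarity_threshold) {
        keep[o] <- FALSE
      }
    }
  }
  cat[keep, , drop = FALSE]
}
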
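# Edge weighting: connected affinity (complex-derived) plus Pearson
# co-expression.  For a known complex k with N_k members and R_k static-PIN
# edges among them, every induced edge receives N_k / R_k; the connected
# affinity coefficient of an edge is the sum of those contributions over all
# complexes containing it.  The final weight is CAC + PCC, and edges with
# non-positive weight are eliminated as likely false positives.

#' Connected affinity coefficients of PIN edges
#'
#' For each complex, R_k counts the static-PIN edges induced on its member
#' set (catalogues list members only, so induced PIN edges are the available
#' notion of "interactions within the complex"); every such edge gains
#' `N_k / R_k` where N_k is the member count.  Complexes inducing no edge
#' contribute nothing (their ratio is undefined) and are counted in the
#' `n_skipped` attribute.  Edges contained in no complex score 0.
#'
#' @param pin Static PIN edge tibble.
#' @param catalog Known-complex catalogue ([complex_catalog()]), or `NULL`
#'   for an all-zero result.
#' @return The PIN tibble with an added `cac` column (>= 0).
#' @export
connected_affinity <- function(pin, catalog = NULL) {
  cac <- numeric(nrow(pin))
  skipped <- 0L
  if (!is.null(catalog) && nrow(catalog) > 0) {
    keys <- edge_key(pin$protein_a, pin$protein_b)
    for (i in seq_len(nrow(catalog))) {
      mem <- catalog$members[[i]]
      nk <- length(mem)
      if (nk < 2) next
      pairs <- utils::combn(sort(mem), 2)
      idx <- match(edge_key(pairs[1, ], pairs[2, ]), keys)
      idx <- idx[!is.na(idx)]
      rk <- length(idx)
      if (rk == 0) {
        skipped <- skipped + 1L
        next
      }
      cac[idx] <- cac[idx] + nk / rk
    }
    if (skipped > 0) {
      message(sprintf("connected_affinity: %d complex(es) induce no PIN edge and were skipped",
                      skipped))
    }
  }
  out <- dplyr::bind_cols(pin, tibble::tibble(cac = cac))
  attr(out, "n_skipped") <- skipped
  out
}

#' Pearson correlation of two expression profiles
#'
#' Standard Pearson correlation over the full time course.  If either
#' profile has zero variance the ratio is 0/0; with no co-expression
#' evidence either way the value is defined as 0.  The result is clamped to
#' `[-1, 1]` against floating-point rounding.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("profile length mismatch", call. = FALSE)
  if (length(x) < 2) stop("profiles need >= 2 time points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  min(1, max(-1, stats::cor(x, y)))
}

#' Weight a temporal network and drop non-positive edges
#'
#' Every snapshot edge receives `W = CAC + PCC`, where PCC is computed once
#' per interaction over the full expression profiles (not per-snapshot
#' windows).  Edges whose endpoints lack expression data take a PCC term of
#' 0, so `W = CAC`.  Edges with `W <= 0` are eliminated as false positives;
#' the per-snapshot elimination ratio (removed / initial edges) is attached
#' as the `elimination` attribute and available via [elimination_ratios()].
#' Snapshot node sets are unchanged.
#'
#' @param net Unweighted `tepin` from [build_tepin()].
#' @param pin Static PIN the network was induced from.
#' @param expr Expression tibble ([read_expression()]).
#' @param catalog Known-complex catalogue, or `NULL` to weight with
#'   co-expression alone (logged).
#' @return A weighted `tepin` whose `edges` carry a `weight` column.
#' @seealso [connected_affinity()], [pearson_cc()]
#' @export
weight_network <- function(net, pin, expr, catalog = NULL) {
  stopifnot(inherits(net, "tepin"))
  if (is.null(catalog)) {
    message("weight_network: no complex catalogue; weights use co-expression only")
  }
  ca <- connected_affinity(pin, catalog)
  pin_keys <- edge_key(ca$protein_a, ca$protein_b)
  m <- expr_matrix(expr)
  sds <- apply(m, 1, stats::sd)
  pcc <- numeric(nrow(ca))
  missing_expr <- 0L
  for (i in seq_len(nrow(ca))) {
    a <- ca$protein_a[i]
    b <- ca$protein_b[i]
    if (!(a %in% rownames(m)) || !(b %in% rownames(m))) {
      missing_expr <- missing_expr + 1L
      next
    }
    if (sds[a] == 0 || sds[b] == 0) next
    pcc[i] <- min(1, max(-1, stats::cor(m[a, ], m[b, ])))
  }
  if (missing_expr > 0) {
    message(sprintf("weight_network: %d PIN edge(s) lack expression for an endpoint; PCC term 0",
                    missing_expr))
  }
  w <- ca$cac + pcc
  idx <- match(edge_key(net$edges$protein_a, net$edges$protein_b), pin_keys)
  if (anyNA(idx)) stop("snapshot edge absent from the static PIN", call. = FALSE)
  ew <- w[idx]
  keep <- ew > 0
  edges <- dplyr::bind_cols(net$edges[keep, , drop = FALSE],
                            tibble::tibble(weight = ew[keep]))
  n <- net$n_timepoints
  initial <- vapply(seq_len(n), function(t) sum(net$edges$timepoint == t), integer(1))
  remaining <- vapply(seq_len(n), function(t) sum(edges$timepoint == t), integer(1))
  elim <- tibble::tibble(timepoint = seq_len(n), n_initial = initial,
                         n_removed = initial - remaining,
                         ratio = ifelse(initial > 0, (initial - remaining) / initial, 0))
  out <- new_tepin(net$nodes, edges, n, weighted = TRUE)
  attr(out, "elimination") <- elim
  out
}

#' Per-snapshot edge elimination ratios
#'
#' @param net Weighted `tepin` from [weight_network()].
#' @return Tibble with columns `timepoint`, `n_initial`, `n_removed`,
#'   `ratio`.
#' @export
elimination_ratios <- function(net) {
  e <- attr(net, "elimination")
  if (is.null(e)) stop("network carries no elimination record; weight it first",
                       call. = FALSE)
  e
}
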
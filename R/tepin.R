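# Construction of the time-evolving network: snapshot t is the subgraph of
# the static PIN induced on the proteins active at t.  Isolated active
# proteins are kept as snapshot nodes (the construction reserves the active
# proteins first, then whatever interactions survive); clustering ignores
# them.

#' Build a time-evolving protein interaction network
#'
#' For every time point t, the snapshot is the static-PIN subgraph induced
#' on the active proteins at t: nodes are active proteins that occur in the
#' PIN, edges are PIN edges with both endpoints active.
#'
#' @param pin Static PIN edge tibble ([read_ppi()]).
#' @param schedule Activity schedule ([activity_profiles()]).
#' @return A `tepin` object: list with `nodes` (tibble `timepoint`,
#'   `protein`), `edges` (tibble `timepoint`, `protein_a`, `protein_b`, plus
#'   `weight` once weighted), `n_timepoints`, and `weighted` flag.
#' @seealso [weight_network()], [mine_temporal_complexes()],
#'   [network_properties()]
#' @export
build_tepin <- function(pin, schedule) {
  n <- attr(schedule, "n_timepoints")
  if (is.null(n)) stop("schedule lacks an n_timepoints attribute", call. = FALSE)
  prots <- pin_proteins(pin)
  sched <- schedule[schedule$gene %in% prots, , drop = FALSE]
  # active indicator matrix: proteins x timepoints
  act <- matrix(FALSE, nrow = length(prots), ncol = n,
                dimnames = list(prots, NULL))
  for (i in seq_len(nrow(sched))) {
    act[sched$gene[i], sched$active[[i]]] <- TRUE
  }
  ia <- match(pin$protein_a, prots)
  ib <- match(pin$protein_b, prots)
  nodes <- vector("list", n)
  edges <- vector("list", n)
  for (t in seq_len(n)) {
    on <- act[, t]
    nodes[[t]] <- tibble::tibble(timepoint = t, protein = prots[on])
    keep <- on[ia] & on[ib]
    edges[[t]] <- tibble::tibble(timepoint = t,
                                 protein_a = pin$protein_a[keep],
                                 protein_b = pin$protein_b[keep])
  }
  new_tepin(dplyr::bind_rows(nodes), dplyr::bind_rows(edges), n, weighted = FALSE)
}

new_tepin <- function(nodes, edges, n_timepoints, weighted) {
  structure(list(nodes = nodes, edges = edges,
                 n_timepoints = as.integer(n_timepoints),
                 weighted = isTRUE(weighted)),
            class = "tepin")
}

#' Treat a static PIN as a one-snapshot network
#'
#' Wraps a static PIN as a `tepin` with a single time point, so the static
#' and temporal analyses share one code path (mining on it equals clustering
#' the PIN directly).
#'
#' @param pin Static PIN edge tibble.
#' @return A `tepin` with `n_timepoints = 1`.
#' @export
as_static_network <- function(pin) {
  prots <- pin_proteins(pin)
  new_tepin(tibble::tibble(timepoint = rep(1L, length(prots)), protein = prots),
            dplyr::bind_cols(tibble::tibble(timepoint = rep(1L, nrow(pin))), pin),
            1L, weighted = FALSE)
}

#' Extract one snapshot's edge table
#'
#' @param net A `tepin`.
#' @param t Time point in `1..n_timepoints`.
#' @return Edge tibble (`protein_a`, `protein_b`, and `weight` if weighted).
#' @export
snapshot_edges <- function(net, t) {
  e <- net$edges[net$edges$timepoint == t,
                 setdiff(names(net$edges), "timepoint"), drop = FALSE]
  tibble::as_tibble(e)
}

#' @export
print.tepin <- function(x, ...) {
  cat(sprintf("Time-evolving PIN: %d snapshot(s), %s\n", x$n_timepoints,
              if (x$weighted) "weighted" else "unweighted"))
  p <- network_properties(x)
  avg <- p[p$snapshot == "average", ]
  cat(sprintf("  average nodes %.1f, edges %.1f, density %.6f\n",
              avg$n_nodes, avg$n_edges, avg$density))
  invisible(x)
}

#' Density of a simple undirected graph
#'
#' `2E / (N (N - 1))`; graphs with fewer than two nodes have density 0.
#'
#' @param n_nodes,n_edges Node and edge counts (vectorised).
#' @return Numeric density values.
#' @examples
#' graph_density(5093, 24743)
#' @export
graph_density <- function(n_nodes, n_edges) {
  ifelse(n_nodes > 1, 2 * n_edges / (n_nodes * (n_nodes - 1)), 0)
}

#' Per-snapshot and average network properties
#'
#' Node count, edge count and density for every snapshot, plus an `average`
#' row holding arithmetic means of the per-snapshot values.  The average
#' density is the mean of per-snapshot densities, not the density of the
#' averaged counts — the two differ because density is nonlinear in N and E.
#' For a static PIN edge tibble a single `static` row is returned.
#'
#' @param net A `tepin` or a static PIN edge tibble.
#' @return Tibble with columns `snapshot`, `n_nodes`, `n_edges`, `density`.
#' @export
network_properties <- function(net) {
  if (!inherits(net, "tepin")) {
    pin <- net
    return(tibble::tibble(snapshot = "static",
                          n_nodes = length(pin_proteins(pin)),
                          n_edges = nrow(pin),
                          density = graph_density(length(pin_proteins(pin)), nrow(pin))))
  }
  n <- net$n_timepoints
  nn <- vapply(seq_len(n), function(t) sum(net$nodes$timepoint == t), integer(1))
  ne <- vapply(seq_len(n), function(t) sum(net$edges$timepoint == t), integer(1))
  dens <- graph_density(nn, ne)
  tibble::tibble(snapshot = c(sprintf("T%d", seq_len(n)), "average"),
                 n_nodes = c(nn, mean(nn)),
                 n_edges = c(ne, mean(ne)),
                 density = c(dens, mean(dens)))
}

#' @export
tidy.tepin <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' @export
glance.tepin <- function(x, ...) {
  p <- network_properties(x)
  avg <- p[p$snapshot == "average", ]
  tibble::tibble(n_timepoints = x$n_timepoints, weighted = x$weighted,
                 avg_nodes = avg$n_nodes, avg_edges = avg$n_edges,
                 avg_density = avg$density)
}

#' Write a temporal network to a directory
#'
#' One edge-list file per snapshot (three columns when weighted), a node
#' list, and a `manifest.tsv` describing the files.
#'
#' @param net A `tepin`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tepin <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(net$n_timepoints)
  for (t in seq_len(net$n_timepoints)) {
    e <- snapshot_edges(net, t)
    files[t] <- sprintf("snapshot_%02d.tsv", t)
    if (net$weighted) {
      writeLines(paste(e$protein_a, e$protein_b, formatC(e$weight, digits = 8, format = "g"),
                       sep = "\t"), file.path(dir, files[t]))
    } else {
      writeLines(paste(e$protein_a, e$protein_b, sep = "\t"), file.path(dir, files[t]))
    }
  }
  nodes <- net$nodes
  writeLines(paste(nodes$timepoint, nodes$protein, sep = "\t"),
             file.path(dir, "nodes.tsv"))
  writeLines(c(sprintf("# weighted\t%s", net$weighted),
               paste(seq_len(net$n_timepoints), files, sep = "\t")),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}
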
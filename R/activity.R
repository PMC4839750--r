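# Active-time-point calling.  The deviation-degree rule declares a gene
# active at time t when its expression there strictly exceeds the gene's own
# mean plus one standard deviation (sample sd, n-1 denominator) over the full
# time course.  A per-gene threshold avoids the failure modes of a single
# global cutoff (constitutively low expressors are never seen; constitutively
# high ones are always "active").

#' Deviation-degree profile of one expression row
#'
#' Computes the gene's arithmetic mean, sample standard deviation, activity
#' threshold (mean + sd), and the set of time points where expression
#' strictly exceeds the threshold.  A constant gene (sd = 0) is never active:
#' no value is strictly above its own mean.
#'
#' @param x Numeric vector of expression values over >= 2 time points.
#' @return A one-row tibble with columns `mean`, `sd`, `threshold`,
#'   `n_active`, and `active` (list column of integer time indices).
#' @examples
#' deviation_degree(c(1, 2, 3, 4, 5, 6))
#' @export
deviation_degree <- function(x) {
  if (length(x) < 2) stop("deviation degree needs >= 2 time points", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite expression value", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  thr <- m + s
  act <- which(x > thr)
  tibble::tibble(mean = m, sd = s, threshold = thr,
                 n_active = length(act), active = list(as.integer(act)))
}

#' Deviation-degree activity detector
#'
#' Detector functions map one expression row to the integer set of active
#' time points; any such function can be passed to [activity_profiles()],
#' which makes it easy to plug in alternative activity rules (e.g. an
#' external three-sigma implementation).
#'
#' @param x Numeric expression vector (length >= 2).
#' @return Integer vector of active time indices.
#' @export
detect_deviation_degree <- function(x) {
  if (length(x) < 2) stop("deviation degree needs >= 2 time points", call. = FALSE)
  as.integer(which(x > mean(x) + stats::sd(x)))
}

#' Global-threshold baseline detector
#'
#' Returns a detector declaring a gene active wherever its expression
#' strictly exceeds a fixed cutoff `c` — the naive baseline that per-gene
#' thresholds are designed to improve on.  With `c = -Inf` every gene is
#' active at every time point.
#'
#' @param threshold Fixed global cutoff.
#' @return A detector function usable with [activity_profiles()].
#' @export
detect_global_threshold <- function(threshold) {
  force(threshold)
  function(x) as.integer(which(x > threshold))
}

#' Activity schedule for all genes of an expression matrix
#'
#' Applies a detector to every gene row and records, alongside the active
#' time-point sets, the deviation-degree summary statistics (mean, sd,
#' threshold) that describe each expression curve.
#'
#' @param expr Expression tibble ([read_expression()]).
#' @param detector Function mapping a numeric row to integer active time
#'   points; default [detect_deviation_degree].
#' @return An activity schedule: tibble with columns `gene`, `mean`, `sd`,
#'   `threshold`, `n_active`, `active` (list of integer vectors), with
#'   attribute `n_timepoints`.
#' @seealso [active_sets()], [activity_histogram()], [build_tepin()]
#' @export
activity_profiles <- function(expr, detector = detect_deviation_degree) {
  m <- expr_matrix(expr)
  n <- ncol(m)
  if (n < 2) stop("activity calling needs >= 2 time points", call. = FALSE)
  act <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    a <- as.integer(detector(m[i, ]))
    if (length(a) && (min(a) < 1 || max(a) > n)) {
      stop("detector returned a time index outside 1..n", call. = FALSE)
    }
    act[[i]] <- sort(a)
  }
  mu <- rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  out <- tibble::tibble(gene = rownames(m), mean = mu, sd = sds,
                        threshold = mu + sds,
                        n_active = lengths(act), active = act)
  attr(out, "n_timepoints") <- n
  out
}

#' Active protein sets per time point
#'
#' Inverts an activity schedule into the sequential collection of active
#' protein sets, one per time point.
#'
#' @param schedule Activity schedule from [activity_profiles()].
#' @param n_timepoints Number of time points; defaults to the schedule's
#'   `n_timepoints` attribute.
#' @return Tibble with columns `timepoint`, `proteins` (list of character
#'   vectors), `n_active`.
#' @export
active_sets <- function(schedule, n_timepoints = NULL) {
  n <- n_timepoints %||% attr(schedule, "n_timepoints")
  if (is.null(n)) stop("n_timepoints not available", call. = FALSE)
  sets <- lapply(seq_len(n), function(t) {
    schedule$gene[vapply(schedule$active, function(a) t %in% a, logical(1))]
  })
  tibble::tibble(timepoint = seq_len(n), proteins = sets, n_active = lengths(sets))
}

#' Distribution of active-time-point counts
#'
#' How many proteins are active at 0, 1, 2, ... time points.  Counts sum to
#' the number of genes in the schedule.
#'
#' @param schedule Activity schedule from [activity_profiles()].
#' @return Tibble with columns `n_active` (0..n) and `n_proteins`.
#' @export
activity_histogram <- function(schedule) {
  n <- attr(schedule, "n_timepoints") %||% max(schedule$n_active, 0L)
  counts <- table(factor(schedule$n_active, levels = 0:n))
  tibble::tibble(n_active = 0:n, n_proteins = as.integer(counts))
}
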
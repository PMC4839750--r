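# Seeded generator of PIN + expression + complex-catalogue triples with
# planted temporal structure: disjoint complexes, clique-ish intra-complex
# wiring, background edge noise, and a contiguous activation window per
# complex during which member genes are boosted and hence co-expressed and
# deviation-degree active.

#' Synthetic-data configuration
#'
#' Defaults describe a strong-signal benchmark: 300 proteins carrying 20
#' disjoint planted complexes of 4-10 members over 36 time points;
#' intra-complex edges drawn with probability 0.9 against a 0.01 background;
#' 5% spurious edge additions and 5% deletions; expression baseline 5 with
#' an activation amplitude of 3 against Gaussian noise of sd 0.5 (a 6x
#' signal-to-noise ratio); contiguous activation windows of 3-8 time points,
#' the range in which most yeast proteins' active-point counts fall.
#'
#' @param n_proteins Total proteins.
#' @param n_complexes Planted complexes (disjoint member sets).
#' @param size_range Two integers: min/max complex size (>= 2).
#' @param n_timepoints Time points in the expression course (default 36).
#' @param p_in,p_out Intra-complex / background edge probabilities.
#' @param fp_rate Spurious edges added, as a fraction of true edges.
#' @param fn_rate Probability that a true edge is deleted.
#' @param baseline,amplitude,noise_sd Expression model: members emit
#'   `baseline + amplitude` inside their complex's window, `baseline`
#'   outside, plus N(0, noise_sd) noise everywhere.
#' @param window_range Two integers: min/max activation-window length.
#' @param seed Integer seed; the whole draw is reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 300, n_complexes = 20,
                         size_range = c(4, 10), n_timepoints = 36,
                         p_in = 0.9, p_out = 0.01,
                         fp_rate = 0.05, fn_rate = 0.05,
                         baseline = 5, amplitude = 3, noise_sd = 0.5,
                         window_range = c(3, 8), seed = 1) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_complexes = as.integer(n_complexes),
              size_range = as.integer(size_range),
              n_timepoints = as.integer(n_timepoints),
              p_in = p_in, p_out = p_out,
              fp_rate = fp_rate, fn_rate = fn_rate,
              baseline = baseline, amplitude = amplitude, noise_sd = noise_sd,
              window_range = as.integer(window_range), seed = as.integer(seed))
  stopifnot(cfg$n_proteins >= 2, cfg$n_complexes >= 1,
            length(cfg$size_range) == 2, cfg$size_range[1] >= 2,
            cfg$size_range[1] <= cfg$size_range[2],
            cfg$n_timepoints >= 2,
            cfg$p_in >= 0, cfg$p_in <= 1, cfg$p_out >= 0, cfg$p_out <= 1,
            cfg$fp_rate >= 0, cfg$fp_rate <= 1, cfg$fn_rate >= 0, cfg$fn_rate <= 1,
            cfg$amplitude >= 0, cfg$noise_sd >= 0,
            length(cfg$window_range) == 2, cfg$window_range[1] >= 1,
            cfg$window_range[1] <= cfg$window_range[2],
            cfg$window_range[2] <= cfg$n_timepoints)
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic PIN / expression / catalogue triple
#'
#' Plants `n_complexes` disjoint complexes, wires intra-complex pairs with
#' probability `p_in` and all other pairs with `p_out`, deletes each true
#' edge with probability `fn_rate` and adds `fp_rate * n_edges` spurious
#' ones.  Every complex receives a contiguous activation window; member
#' genes' expression is `baseline + amplitude` inside the window and
#' `baseline` outside, plus Gaussian noise, giving both co-expression and
#' deviation-degree activity inside the window.  The annotation map carries
#' one functional term per planted complex with genome size `n_proteins`.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List with elements `pin` (edge tibble), `expr` (expression
#'   tibble covering all proteins), `known` (catalogue handed to weighting
#'   and evaluation), `truth` (planted catalogue; identical to `known`),
#'   `annotation`, and `windows` (tibble of per-complex activation windows).
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_complexes * config$size_range[2] > config$n_proteins) {
    # sizes are drawn before membership; require feasibility in the worst case
    stop("complexes cannot be disjoint: n_complexes * max size exceeds n_proteins",
         call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_proteins
  prot <- sprintf("P%04d", seq_len(n))

  sizes <- sample(seq(config$size_range[1], config$size_range[2]),
                  config$n_complexes, replace = TRUE)
  pool <- sample(prot)
  members <- vector("list", config$n_complexes)
  pos <- 1
  for (k in seq_len(config$n_complexes)) {
    members[[k]] <- sort(pool[pos:(pos + sizes[k] - 1)])
    pos <- pos + sizes[k]
  }
  names(members) <- sprintf("K%02d", seq_len(config$n_complexes))
  cid <- integer(n)  # complex id per protein, 0 = background
  for (k in seq_along(members)) cid[match(members[[k]], prot)] <- k

  pairs <- utils::combn(n, 2)
  same <- cid[pairs[1, ]] != 0 & cid[pairs[1, ]] == cid[pairs[2, ]]
  p_edge <- ifelse(same, config$p_in, config$p_out)
  present <- stats::runif(ncol(pairs)) < p_edge
  n_true <- sum(present)
  # false negatives: delete true edges
  if (config$fn_rate > 0 && n_true > 0) {
    present[present] <- stats::runif(n_true) >= config$fn_rate
  }
  # false positives: add spurious non-edges
  n_fp <- round(config$fp_rate * n_true)
  absent_idx <- which(!present)
  if (n_fp > 0 && length(absent_idx) > 0) {
    present[sample(absent_idx, min(n_fp, length(absent_idx)))] <- TRUE
  }
  pin <- as_pin(tibble::tibble(protein_a = prot[pairs[1, present]],
                               protein_b = prot[pairs[2, present]]))

  nt <- config$n_timepoints
  wlen <- sample(seq(config$window_range[1], config$window_range[2]),
                 config$n_complexes, replace = TRUE)
  wstart <- vapply(wlen, function(l) sample(nt - l + 1, 1), integer(1))
  windows <- tibble::tibble(complex = names(members),
                            start = wstart, end = wstart + wlen - 1L)
  vals <- matrix(config$baseline, nrow = n, ncol = nt,
                 dimnames = list(prot, sprintf("T%d", seq_len(nt))))
  for (k in seq_along(members)) {
    rows <- match(members[[k]], prot)
    vals[rows, wstart[k]:(wstart[k] + wlen[k] - 1)] <-
      vals[rows, wstart[k]:(wstart[k] + wlen[k] - 1)] + config$amplitude
  }
  if (config$noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(n * nt, 0, config$noise_sd), n, nt)
  }
  expr <- dplyr::bind_cols(tibble::tibble(gene = prot), tibble::as_tibble(vals))

  truth <- complex_catalog(members)
  ann <- tibble::tibble(term = sprintf("F%02d", seq_along(members)),
                        members = unname(members), size = lengths(members))
  attr(ann, "genome_size") <- n

  list(pin = pin, expr = expr, known = truth, truth = truth,
       annotation = ann, windows = windows)
}

#' Planted-complex recovery: weighted temporal vs static pipeline
#'
#' Generates one synthetic data set, runs the full weighted time-evolving
#' pipeline (activity calling, snapshot construction, weighting, per-snapshot
#' Markov clustering, merge and redundancy filtering) and the static-PIN
#' pipeline (one clustering of the whole PIN with identical parameters and
#' filtering), and evaluates both predictions against the planted catalogue
#' at the given overlap-score threshold.
#'
#' @param config A [synth_config()].
#' @param os_threshold Match threshold (default 0.2).
#' @param similarity_threshold Redundancy threshold (default 1.0).
#' @param params [mcl_params()] shared by both pipelines.
#' @return List with `weighted_tepin` and `static` accuracy rows
#'   ([accuracy_metrics()]) and `f_difference` (weighted minus static
#'   F-measure).
#' @export
recovery_experiment <- function(config = synth_config(), os_threshold = 0.2,
                                similarity_threshold = 1,
                                params = mcl_params()) {
  data <- generate_synthetic(config)
  sched <- activity_profiles(data$expr)
  net <- build_tepin(data$pin, sched)
  wnet <- weight_network(net, data$pin, data$expr, data$known)
  pred_w <- mine_temporal_complexes(wnet, mcl_cluster,
                                    similarity_threshold = similarity_threshold,
                                    params = params)
  pred_s <- mine_temporal_complexes(as_static_network(data$pin), mcl_cluster,
                                    similarity_threshold = similarity_threshold,
                                    params = params)
  mw <- match_complexes(pred_w, data$known, os_threshold)
  ms <- match_complexes(pred_s, data$known, os_threshold)
  rw <- suppressWarnings(accuracy_metrics(mw))
  rs <- suppressWarnings(accuracy_metrics(ms))
  list(weighted_tepin = rw, static = rs,
       f_difference = rw$f_measure - rs$f_measure)
}
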
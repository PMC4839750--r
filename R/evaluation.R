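# Evaluation of predicted complexes against a reference catalogue: overlap
# score matching, TP/FP/FN bookkeeping, sensitivity/specificity/F-measure,
# perfect matches, matched-known percentages, and exact hypergeometric
# function enrichment.

#' Overlap score between two complexes
#'
#' `OS(pc, kc) = |pc \ intersect kc|^2 / (|pc| * |kc|)`.  Symmetric, in
#' `[0, 1]`, and equal to 1 exactly when the sets coincide.
#'
#' @param pc,kc Non-empty character vectors of member IDs.
#' @return Overlap score in `[0, 1]`.
#' @examples
#' overlap_score(c("A", "B", "C", "D"), c("A", "B", "C"))  # 9/12
#' @export
overlap_score <- function(pc, kc) {
  pc <- unique(pc)
  kc <- unique(kc)
  if (length(pc) == 0 || length(kc) == 0) {
    stop("overlap score of an empty complex is undefined", call. = FALSE)
  }
  length(intersect(pc, kc))^2 / (length(pc) * length(kc))
}

#' Match predicted complexes against known complexes
#'
#' Computes all pairwise overlap scores; a predicted/known pair is matched
#' when OS reaches `os_threshold`.  TP counts predicted complexes matching
#' at least one known complex (once, however many they match), FP the rest;
#' MKC counts known complexes matched by at least one prediction, FN the
#' rest (`FN = |known| - MKC`); perfect matches are known complexes attaining
#' OS = 1 with some prediction.
#'
#' @param predicted,known Complex catalogues ([complex_catalog()]).
#' @param os_threshold Match threshold in (0, 1]; the conventional default
#'   is 0.2.
#' @return A `complex_match` object; see [accuracy_metrics()] (also its
#'   `glance()` method) and `tidy()` for the matched pairs.
#' @export
match_complexes <- function(predicted, known, os_threshold = 0.2) {
  stopifnot(os_threshold > 0, os_threshold <= 1)
  np <- nrow(predicted)
  nk <- nrow(known)
  p_hit <- rep(FALSE, np)
  k_hit <- rep(FALSE, nk)
  k_perfect <- rep(FALSE, nk)
  pairs <- list()
  for (i in seq_len(np)) {
    for (j in seq_len(nk)) {
      os <- overlap_score(predicted$members[[i]], known$members[[j]])
      if (os >= os_threshold) {
        p_hit[i] <- TRUE
        k_hit[j] <- TRUE
        if (os >= 1 - 1e-12) k_perfect[j] <- TRUE
        pairs[[length(pairs) + 1]] <-
          tibble::tibble(predicted = predicted$complex[i],
                         known = known$complex[j], os = os)
      }
    }
  }
  match_result(
    tp = sum(p_hit), fp = np - sum(p_hit),
    fn = nk - sum(k_hit), mkc = sum(k_hit), perfect = sum(k_perfect),
    os_threshold = os_threshold,
    avg_predicted_size = if (np > 0) mean(predicted$size) else NA_real_,
    pairs = if (length(pairs)) dplyr::bind_rows(pairs) else
      tibble::tibble(predicted = character(), known = character(), os = numeric())
  )
}

#' Construct a match result from counts
#'
#' Useful for accuracy arithmetic over published tables, where only the
#' counts (TP, FP, FN, MKC, perfect matches) are available.
#'
#' @param tp,fp Matched / unmatched predicted complex counts
#'   (`tp + fp` = number of predictions).
#' @param fn Known complexes matched by no prediction.
#' @param mkc Known complexes matched by >= 1 prediction; `mkc + fn` =
#'   catalogue size.
#' @param perfect Known complexes attaining OS = 1.
#' @param os_threshold Threshold the counts were computed at.
#' @param avg_predicted_size Mean predicted-complex size, if known.
#' @param pairs Optional tibble of matched pairs.
#' @return A `complex_match` object.
#' @export
match_result <- function(tp, fp, fn, mkc = NA_integer_, perfect = NA_integer_,
                         os_threshold = 0.2, avg_predicted_size = NA_real_,
                         pairs = NULL) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, mkc = mkc, perfect = perfect,
                 n_predicted = tp + fp,
                 n_known = if (is.na(mkc)) NA_integer_ else mkc + fn,
                 os_threshold = os_threshold,
                 avg_predicted_size = avg_predicted_size,
                 pairs = pairs),
            class = "complex_match")
}

#' @export
print.complex_match <- function(x, ...) {
  cat(sprintf("Complex match at OS >= %.2g: %d predicted, %s known\n",
              x$os_threshold, x$n_predicted,
              if (is.na(x$n_known)) "?" else x$n_known))
  cat(sprintf("  TP %d  FP %d  FN %d  MKC %s  perfect %s\n",
              x$tp, x$fp, x$fn, x$mkc, x$perfect))
  invisible(x)
}

#' @export
tidy.complex_match <- function(x, ...) {
  x$pairs %||% tibble::tibble(predicted = character(), known = character(),
                              os = numeric())
}

#' Accuracy metrics from a match result
#'
#' `Sn = TP / (TP + FN)`, `Sp = TP / (TP + FP)`, and their harmonic mean
#' (the F-measure).  A zero denominator yields 0 with a warning.
#'
#' @param match A `complex_match` ([match_complexes()] or [match_result()]).
#' @return One-row tibble: counts plus `sn`, `sp`, `f_measure`,
#'   `avg_predicted_size`, `matched_known_pct`.
#' @export
accuracy_metrics <- function(match) {
  stopifnot(inherits(match, "complex_match"))
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      warning(what, ": zero denominator, reporting 0", call. = FALSE)
      0
    } else num / den
  }
  sn <- ratio0(match$tp, match$tp + match$fn, "Sn")
  sp <- ratio0(match$tp, match$tp + match$fp, "Sp")
  f <- if (sn + sp > 0) 2 * sn * sp / (sn + sp) else 0
  tibble::tibble(
    n_predicted = match$n_predicted, n_known = match$n_known,
    tp = match$tp, fp = match$fp, fn = match$fn,
    mkc = match$mkc, perfect = match$perfect,
    sn = sn, sp = sp, f_measure = f,
    avg_predicted_size = match$avg_predicted_size,
    matched_known_pct = if (is.na(match$mkc) || is.na(match$n_known) ||
                            match$n_known == 0) NA_real_ else
      100 * match$mkc / match$n_known
  )
}

#' @export
glance.complex_match <- function(x, ...) accuracy_metrics(x)

#' Percentage of known complexes matched
#'
#' @param match A `complex_match`, or directly the MKC count.
#' @param total_known Size of the known catalogue; defaults to the match
#'   result's catalogue size.
#' @return `100 * MKC / total_known`.
#' @examples
#' matched_known_percentage(505, 1063)
#' @export
matched_known_percentage <- function(match, total_known = NULL) {
  mkc <- if (inherits(match, "complex_match")) match$mkc else match
  total <- total_known %||%
    (if (inherits(match, "complex_match")) match$n_known else NULL)
  if (is.null(total) || is.na(total)) stop("total_known is required", call. = FALSE)
  if (total == 0) stop("total_known must be positive", call. = FALSE)
  if (total < mkc) stop("total_known smaller than MKC", call. = FALSE)
  100 * mkc / total
}

#' Exact hypergeometric enrichment p-value
#'
#' Probability of observing `k` or more proteins of a `C`-member complex in
#' a functional class of `F` proteins drawn from a genome of `N`:
#' the upper tail `P(X >= k)` of Hypergeometric(N, F, C), evaluated exactly
#' as a log-space sum of terms `choose(F, i) choose(N - F, C - i) /
#' choose(N, C)` (no normal approximation), so values far below double
#' precision of `1 - cdf` are still exact.
#'
#' @param k Overlap count(s), `0 <= k <= C`.
#' @param C Complex size(s), `<= N`.
#' @param F_ Functional class size(s) `F`, `<= N`.
#' @param N Genome size(s).
#' @return p-value(s) in `[0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' enrichment_pvalue(2, 2, 5, 10)  # 10/45
#' @export
enrichment_pvalue <- function(k, C, F_, N) {
  n <- max(length(k), length(C), length(F_), length(N))
  k <- rep_len(as.numeric(k), n)
  C <- rep_len(as.numeric(C), n)
  F_ <- rep_len(as.numeric(F_), n)
  N <- rep_len(as.numeric(N), n)
  if (any(k < 0 | k > C | C > N | F_ < 0 | F_ > N)) {
    stop("require 0 <= k <= C <= N and 0 <= F <= N", call. = FALSE)
  }
  vapply(seq_len(n), function(j) {
    if (k[j] == 0) return(1)
    i <- seq(k[j], min(C[j], F_[j]))
    if (length(i) == 0 || i[1] > min(C[j], F_[j])) return(0)
    lt <- lchoose(F_[j], i) + lchoose(N[j] - F_[j], C[j] - i) - lchoose(N[j], C[j])
    lt <- lt[is.finite(lt)]
    if (length(lt) == 0) return(0)
    mx <- max(lt)
    min(1, exp(mx) * sum(exp(lt - mx)))
  }, numeric(1))
}

enrichment_bin_breaks <- c(-Inf, 1e-15, 1e-10, 1e-5, 0.01, Inf)
enrichment_bin_labels <- c("<1e-15", "[1e-15,1e-10)", "[1e-10,1e-5)",
                           "[1e-5,0.01)", ">=0.01")

#' Annotate predicted complexes with their best-enriched term
#'
#' For each complex, evaluates the hypergeometric enrichment p-value against
#' every functional term and keeps the smallest.  Complexes with no
#' annotated member get p = 1 and are flagged as not significant.  Each
#' complex is also binned into the conventional p-value intervals
#' `<1e-15, [1e-15,1e-10), [1e-10,1e-5), [1e-5,0.01), >=0.01`.
#'
#' @param predicted Predicted-complex catalogue.
#' @param annotation Annotation map ([read_annotation()]).
#' @param alpha Significance level; a complex with `p >= alpha` carries no
#'   statistical support (default 0.01).
#' @param genome_size Genome size `N`; defaults to the annotation's
#'   `genome_size` attribute (itself defaulting to the annotated universe).
#' @return Tibble: `complex`, `size`, `term` (best term or NA), `p_value`,
#'   `significant`, `bin`.
#' @export
annotate_complexes <- function(predicted, annotation, alpha = 0.01,
                               genome_size = NULL) {
  N <- genome_size %||% attr(annotation, "genome_size") %||%
    length(unique(unlist(annotation$members)))
  res <- lapply(seq_len(nrow(predicted)), function(i) {
    mem <- predicted$members[[i]]
    C <- length(mem)
    best_p <- 1
    best_term <- NA_character_
    for (j in seq_len(nrow(annotation))) {
      kk <- length(intersect(mem, annotation$members[[j]]))
      if (kk == 0) next
      p <- enrichment_pvalue(kk, C, annotation$size[j], N)
      if (p < best_p) {
        best_p <- p
        best_term <- annotation$term[j]
      }
    }
    tibble::tibble(complex = predicted$complex[i], size = C,
                   term = best_term, p_value = best_p)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(complex = character(), size = integer(),
                          term = character(), p_value = numeric())
  }
  out$significant <- out$p_value < alpha
  out$bin <- cut(out$p_value, breaks = enrichment_bin_breaks,
                 labels = enrichment_bin_labels, right = FALSE)
  out
}

#' Bin annotated complexes by p-value interval
#'
#' @param annotated Output of [annotate_complexes()] (needs a `p_value`
#'   column).
#' @return Tibble with one row per interval: `bin`, `n`, `pct` (of all
#'   complexes).
#' @export
enrichment_bins <- function(annotated) {
  bin <- cut(annotated$p_value, breaks = enrichment_bin_breaks,
             labels = enrichment_bin_labels, right = FALSE)
  counts <- table(bin)
  tibble::tibble(bin = names(counts), n = as.integer(counts),
                 pct = if (sum(counts) > 0) 100 * as.integer(counts) / sum(counts)
                 else rep(NA_real_, length(counts)))
}

#' Summary of an enrichment analysis
#'
#' @param annotated Output of [annotate_complexes()].
#' @param alpha Significance level (default 0.01).
#' @return One-row tibble: `n_complexes`, `n_significant`,
#'   `pct_significant`.
#' @export
enrichment_summary <- function(annotated, alpha = 0.01) {
  n <- nrow(annotated)
  sig <- sum(annotated$p_value < alpha)
  tibble::tibble(n_complexes = n, n_significant = sig,
                 pct_significant = if (n > 0) 100 * sig / n else NA_real_)
}
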
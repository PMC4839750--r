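# Readers/writers for the simple TSV dialects used throughout: a DIP-style
# two-column edge list, an expression TSV (header of time labels, one row per
# gene), MIPS-style one-complex-per-line member lists, and a term->members
# annotation table.  All are UTF-8, '#' starts a comment line.

# returns data.frame(line_no, text) of non-comment lines; blank lines are
# dropped but counted so callers can warn (the complex format treats them
# as skipped records)
read_data_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  line_no <- seq_along(raw)
  keep <- !grepl("^\\s*#", raw)
  raw <- raw[keep]
  line_no <- line_no[keep]
  blank <- !nzchar(trimws(raw))
  structure(
    data.frame(line_no = line_no[!blank], text = raw[!blank],
               stringsAsFactors = FALSE),
    n_blank = sum(blank)
  )
}

split_fields <- function(x) strsplit(trimws(x), "[ \t]+")

#' Read a static protein interaction network
#'
#' Parses a two-or-more-column whitespace/tab separated edge list (the first
#' two fields of each line are protein IDs).  Self-interactions and repeated
#' pairs are removed: a protein appearing only in self-loops does not enter
#' the node set, matching the usual preprocessing of curated interaction
#' downloads.  Edges are canonicalised so that `protein_a < protein_b` and
#' sorted, making the reader deterministic.
#'
#' @param path Path to the edge-list file.  Lines starting with `#` are
#'   comments.
#' @return A tibble with columns `protein_a`, `protein_b`, one row per
#'   distinct interaction.  Attributes `n_self_loops` and `n_duplicates`
#'   record how many records were dropped.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "C\tC"), f)
#' read_ppi(f)
#' @seealso [write_ppi()], [pin_proteins()]
#' @export
read_ppi <- function(path) {
  ln <- read_data_lines(path)
  if (nrow(ln) == 0) stop("empty PPI file: ", path, call. = FALSE)
  fields <- split_fields(ln$text)
  bad <- lengths(fields) < 2
  if (any(bad)) {
    stop(sprintf("malformed PPI line %d: fewer than 2 fields",
                 ln$line_no[which(bad)[1]]), call. = FALSE)
  }
  a <- vapply(fields, `[`, character(1), 1)
  b <- vapply(fields, `[`, character(1), 2)
  self <- a == b
  a2 <- a[!self]
  b2 <- b[!self]
  dup <- duplicated(edge_key(a2, b2))
  pin <- as_pin(tibble::tibble(protein_a = a2[!dup], protein_b = b2[!dup]))
  attr(pin, "n_self_loops") <- sum(self)
  attr(pin, "n_duplicates") <- sum(dup)
  if (sum(self) + sum(dup) > 0) {
    message(sprintf("read_ppi: dropped %d self-loop(s) and %d duplicate edge(s)",
                    sum(self), sum(dup)))
  }
  pin
}

#' Canonicalise an edge table into a static PIN
#'
#' Orders each edge so `protein_a < protein_b`, removes self-loops and
#' duplicate unordered pairs, and sorts rows.
#'
#' @param edges A data frame with character columns `protein_a`, `protein_b`.
#' @return A tibble of distinct canonical edges.
#' @export
as_pin <- function(edges) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(edges)))
  a <- as.character(edges$protein_a)
  b <- as.character(edges$protein_b)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  out <- tibble::tibble(protein_a = pmin(a, b), protein_b = pmax(a, b))
  out <- dplyr::distinct(out)
  dplyr::arrange(out, .data$protein_a, .data$protein_b)
}

#' Proteins of a static PIN
#'
#' @param pin An edge tibble as returned by [read_ppi()].
#' @return Sorted character vector of distinct interacting proteins.
#' @export
pin_proteins <- function(pin) {
  sort(unique(c(pin$protein_a, pin$protein_b)))
}

#' Write a static PIN edge list
#'
#' @param pin Edge tibble from [read_ppi()]/[as_pin()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(pin, path) {
  writeLines(paste(pin$protein_a, pin$protein_b, sep = "\t"), path)
  invisible(path)
}

#' Read a gene expression time course
#'
#' Expects a header row of time-point labels (optionally preceded by a name
#' for the gene-ID column) and one row per gene: the gene ID followed by one
#' numeric expression value per time point.  Rows sharing a gene ID — e.g.
#' several probes mapping to one gene — are collapsed to their per-time-point
#' arithmetic mean with a warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble whose first column is `gene` and whose remaining columns
#'   (one per time point, in time order) are numeric.
#' @seealso [expr_matrix()], [write_expression()]
#' @export
read_expression <- function(path) {
  ln <- read_data_lines(path)
  if (nrow(ln) < 2) stop("expression file needs a header and >= 1 data row: ",
                         path, call. = FALSE)
  fields <- split_fields(ln$text)
  header <- fields[[1]]
  rows <- fields[-1]
  row_no <- ln$line_no[-1]
  width <- lengths(rows)
  if (length(unique(width)) != 1) {
    bad <- which(width != width[1])[1]
    stop(sprintf("ragged expression row at line %d: %d fields, expected %d",
                 row_no[bad], width[bad], width[1]), call. = FALSE)
  }
  n <- width[1] - 1L
  if (n < 1) stop("expression rows need a gene ID plus >= 1 value", call. = FALSE)
  labels <- if (length(header) == width[1]) header[-1] else header
  if (length(labels) != n) {
    stop(sprintf("header has %d time labels but rows carry %d values",
                 length(labels), n), call. = FALSE)
  }
  genes <- vapply(rows, `[`, character(1), 1)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = n)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1]))
    if (anyNA(v) || any(!is.finite(v))) {
      j <- which(is.na(v) | !is.finite(v))[1]
      stop(sprintf("non-numeric expression value at line %d, column %d",
                   row_no[i], j + 1L), call. = FALSE)
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    warning(sprintf("read_expression: %d duplicate gene ID row(s) collapsed to mean profiles",
                    n_dup), call. = FALSE)
    vals <- rowsum(vals, genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  colnames(vals) <- labels
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(vals))
}

#' Expression tibble to numeric matrix
#'
#' @param expr Tibble from [read_expression()] (`gene` column + time columns).
#' @return Numeric matrix, genes in rows (rownames), time points in columns.
#' @export
expr_matrix <- function(expr) {
  stopifnot("gene" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

#' Write an expression time course
#'
#' @param expr Tibble from [read_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  m <- expr_matrix(expr)
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             paste(expr$gene, apply(m, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a complex catalogue
#'
#' One complex per line: a label field followed by tab/space-separated member
#' IDs.  Duplicate members within a line are collapsed; complexes with fewer
#' than `min_size` distinct members are dropped (the usual benchmark
#' preprocessing excludes single-protein "complexes").
#'
#' @param path Path to the catalogue file.
#' @param min_size Minimum complex size retained (default 2).
#' @return A complex catalogue: tibble with columns `complex` (label),
#'   `members` (list of character vectors) and `size`.
#' @seealso [complex_catalog()], [write_complexes()]
#' @export
read_complexes <- function(path, min_size = 2) {
  ln <- read_data_lines(path)
  if (attr(ln, "n_blank") > 0) {
    warning(sprintf("read_complexes: skipped %d empty line(s)", attr(ln, "n_blank")),
            call. = FALSE)
  }
  fields <- split_fields(ln$text)
  labels <- vapply(fields, `[`, character(1), 1)
  members <- lapply(fields, function(f) unique(f[-1]))
  sizes <- lengths(members)
  small <- sizes < min_size
  if (any(small)) {
    message(sprintf("read_complexes: dropped %d complex(es) with < %d members",
                    sum(small), min_size))
  }
  if (anyDuplicated(labels[!small])) {
    stop("duplicate complex label: ", labels[!small][duplicated(labels[!small])][1],
         call. = FALSE)
  }
  complex_catalog(stats::setNames(members[!small], labels[!small]),
                  min_size = min_size)
}

#' Build a complex catalogue from a named list
#'
#' @param x Named list of character vectors (complex label -> member IDs), or
#'   a tibble already holding `complex` and `members` columns.
#' @param min_size Minimum size retained; smaller sets are dropped silently
#'   (use [read_complexes()] for logged file input).
#' @return Catalogue tibble with columns `complex`, `members`, `size`.
#' @export
complex_catalog <- function(x, min_size = 2) {
  if (is.data.frame(x)) {
    out <- tibble::tibble(complex = as.character(x$complex),
                          members = lapply(x$members, function(m) unique(as.character(m))))
  } else {
    if (is.null(names(x))) {
      names(x) <- if (length(x)) sprintf("C%04d", seq_along(x)) else character(0)
    }
    out <- tibble::tibble(complex = names(x),
                          members = unname(lapply(x, function(m) unique(as.character(m)))))
  }
  out$size <- unname(lengths(out$members))
  out <- out[out$size >= min_size, , drop = FALSE]
  if (anyDuplicated(out$complex)) stop("duplicate complex labels", call. = FALSE)
  out
}

#' Write a complex catalogue
#'
#' One complex per line: label, then members sorted alphabetically, so
#' `read_complexes(write_complexes(x))` restores `x` up to member order.
#'
#' @param catalog Catalogue tibble ([complex_catalog()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(catalog, path) {
  lines <- vapply(seq_len(nrow(catalog)), function(i) {
    paste(c(catalog$complex[i], sort(catalog$members[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a functional annotation map
#'
#' One term per line: term ID then member protein IDs.  Used for
#' hypergeometric function-enrichment of predicted complexes; the genome
#' size defaults to the number of distinct annotated proteins and can be
#' overridden when the annotation covers only part of the genome.
#'
#' @param path Path to the term -> members TSV.
#' @param genome_size Optional total genome size `N`; must be at least the
#'   number of distinct annotated proteins.
#' @return Tibble with columns `term`, `members`, `size`, carrying a
#'   `genome_size` attribute.
#' @export
read_annotation <- function(path, genome_size = NULL) {
  ln <- read_data_lines(path)
  fields <- split_fields(ln$text)
  terms <- vapply(fields, `[`, character(1), 1)
  members <- lapply(fields, function(f) unique(f[-1]))
  if (any(lengths(members) == 0)) {
    stop("annotation term with no members at line ",
         ln$line_no[which(lengths(members) == 0)[1]], call. = FALSE)
  }
  if (anyDuplicated(terms)) stop("duplicate annotation term", call. = FALSE)
  out <- tibble::tibble(term = terms, members = members, size = lengths(members))
  universe <- length(unique(unlist(members)))
  gs <- genome_size %||% universe
  if (gs < universe) {
    stop(sprintf("genome_size (%d) smaller than annotated universe (%d)",
                 gs, universe), call. = FALSE)
  }
  attr(out, "genome_size") <- as.integer(gs)
  out
}

#' Write a functional annotation map
#'
#' @param annotation Tibble from [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    paste(c(annotation$term[i], sort(annotation$members[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
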
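#' Construct a partition of a chip grid
#'
#' A partition assigns every chip an integer category label in `1..n`.
#' `n` is the declared category count; categories may be empty (an optimizer
#' centroid can capture no chip), so `n` may exceed the number of labels in
#' use.
#'
#' @param labels integer vector, one label per chip id (position i = chip i).
#' @param n declared number of categories (default: `max(labels)`).
#' @return an integer vector of class `chip_partition` with attribute `n`.
#' @export
chip_partition <- function(labels, n = max(labels)) {
  labels <- as.integer(labels)
  n <- as.integer(n)
  if (n < 1L) cp_stop("n must be >= 1", "colorpart_domain_error")
  if (anyNA(labels) || any(labels < 1L) || any(labels > n))
    cp_stop("labels must lie in 1..n with no missing chips",
            "colorpart_domain_error")
  structure(labels, n = n, class = "chip_partition")
}

#' @export
print.chip_partition <- function(x, ...) {
  cat(sprintf("chip_partition: %d chips, n = %d declared (%d non-empty)\n",
              length(x), attr(x, "n"), length(unique(unclass(x)))))
  invisible(x)
}

n_categories <- function(p) attr(p, "n")

#' Construct a naming system
#'
#' A naming system maps every chip of a grid to a color term (a string).
#' Its induced partition assigns integer labels by order of first occurrence
#' of each term along increasing chip id.
#'
#' @param terms character vector, one term per chip id.
#' @param language free-text tag.
#' @return an object of class `naming_system`.
#' @export
naming_system <- function(terms, language = "") {
  terms <- as.character(terms)
  if (anyNA(terms) || any(!nzchar(terms)))
    cp_stop("every chip must carry a non-empty term", "colorpart_coverage_error")
  structure(terms, language = language, class = "naming_system")
}

#' @export
print.naming_system <- function(x, ...) {
  lang <- attr(x, "language")
  cat(sprintf("naming_system%s: %d chips, %d distinct terms\n",
              if (nzchar(lang)) paste0(" [", lang, "]") else "",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Induced partition of a naming system
#'
#' @param x a `naming_system` (or an object coercible to `chip_partition`).
#' @param ... unused.
#' @return a [chip_partition()] with `n` = number of distinct terms.
#' @export
as_partition <- function(x, ...) UseMethod("as_partition")

#' @export
as_partition.chip_partition <- function(x, ...) x

#' @export
as_partition.naming_system <- function(x, ...) {
  terms <- unclass(x)
  first <- unique(terms)              # order of first occurrence
  chip_partition(match(terms, first), n = length(first))
}

#' @export
as_partition.integer <- function(x, ...) chip_partition(x)

#' @export
as_partition.numeric <- function(x, ...) chip_partition(as.integer(x))

#' Read a naming table
#'
#' Expects a CSV/TSV with a header and two columns `chip_id, term` (extra
#' columns ignored), one row per chip of the target grid.
#'
#' @param path input path (field separator sniffed from the header line).
#' @param grid optional [chip_grid()]; when supplied, the table must cover
#'   exactly the grid's chips.
#' @param language tag stored on the result.
#' @return a [naming_system()].
#' @export
read_naming_table <- function(path, grid = NULL, language = "") {
  if (!file.exists(path))
    cp_stop(sprintf("file not found: %s", path), "colorpart_io_error")
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("chip_id", "term") %in% names(d)))
    cp_stop("naming table requires columns chip_id, term",
            "colorpart_format_error")
  ids <- as.integer(d$chip_id)
  if (anyNA(ids)) cp_stop("non-integer chip_id", "colorpart_format_error")
  if (anyDuplicated(ids))
    cp_stop("duplicate chip_id in naming table", "colorpart_format_error")
  N <- if (is.null(grid)) max(ids) else nrow(grid)
  if (!is.null(grid) && any(!ids %in% grid$id))
    cp_stop("naming table refers to chip ids absent from the grid",
            "colorpart_format_error")
  if (!setequal(ids, seq_len(N)))
    cp_stop(sprintf("naming table covers %d of %d chips", length(ids), N),
            "colorpart_coverage_error")
  terms <- character(N)
  terms[ids] <- as.character(d$term)
  naming_system(terms, language = language)
}

#' Write a naming system (or partition) as a two-column CSV
#'
#' @param x a `naming_system` or `chip_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_naming_table <- function(x, path) {
  if (inherits(x, "chip_partition")) {
    d <- data.frame(chip_id = seq_along(x), term = as.integer(x))
  } else {
    d <- data.frame(chip_id = seq_along(x), term = unclass(x))
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mode map of multi-speaker naming responses
#'
#' Collapses a table of per-speaker naming responses to the modal (most
#' frequent) term per chip.  Ties are broken by lexicographic order of the
#' term string, which makes the result independent of speaker order.
#'
#' @param responses data frame with columns `speaker`, `chip_id`, `term`.
#' @param grid optional [chip_grid()] for coverage checking.
#' @param language tag stored on the result.
#' @return a [naming_system()].
#' @export
mode_map <- function(responses, grid = NULL, language = "") {
  need <- c("speaker", "chip_id", "term")
  if (!all(need %in% names(responses)))
    cp_stop("responses require columns speaker, chip_id, term",
            "colorpart_format_error")
  ids <- as.integer(responses$chip_id)
  N <- if (is.null(grid)) max(ids) else nrow(grid)
  if (!setequal(unique(ids), seq_len(N)))
    cp_stop("some chips have zero responses", "colorpart_coverage_error")
  terms <- character(N)
  for (i in seq_len(N)) {
    tab <- table(responses$term[ids == i])
    best <- names(tab)[tab == max(tab)]
    terms[i] <- sort(best)[1L]        # lexicographic tie-break
  }
  naming_system(terms, language = language)
}
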
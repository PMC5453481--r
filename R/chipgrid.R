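#' Construct a chip grid
#'
#' A chip grid is the palette under study: an ordered set of color chips,
#' each with a position on a Munsell-style chart (a lightness row and a
#' cyclic hue column, or an achromatic slot) and CIELAB coordinates.  The
#' canonical palette of cross-linguistic color surveys has 330 chips: 320
#' chromatic chips in an 8-row by 40-column sheet plus 10 achromatic chips.
#'
#' @param id integer chip ids, unique and dense (1..N).
#' @param row integer lightness row (0-based).
#' @param col integer hue column, 1..C for chromatic chips, 0 for achromatic.
#' @param L,a,b CIELAB coordinates.
#' @return an object of class `chip_grid`: a data frame with columns
#'   `id, row, col, achromatic, L, a, b`, ordered by id.
#' @seealso [read_chip_coordinates()], [synth_grid()]
#' @export
chip_grid <- function(id, row, col, L, a, b) {
  id <- as.integer(id)
  g <- data.frame(id = id, row = as.integer(row), col = as.integer(col),
                  achromatic = as.integer(col) == 0L,
                  L = as.numeric(L), a = as.numeric(a), b = as.numeric(b))
  g <- g[order(g$id), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("chip_grid", "data.frame")
  validate_chip_grid(g)
  g
}

validate_chip_grid <- function(g) {
  if (anyDuplicated(g$id))
    cp_stop("duplicate chip ids", "colorpart_format_error")
  if (!identical(g$id, seq_len(nrow(g))))
    cp_stop("chip ids must be dense 1..N", "colorpart_format_error")
  if (any(!is.finite(g$L)) || any(!is.finite(g$a)) || any(!is.finite(g$b)))
    cp_stop("non-finite CIELAB coordinate", "colorpart_format_error")
  pos <- g[!g$achromatic, c("row", "col")]
  if (nrow(pos) && anyDuplicated(pos))
    cp_stop("chromatic (row, col) positions must be unique",
            "colorpart_format_error")
  invisible(g)
}

#' @export
print.chip_grid <- function(x, ...) {
  cat(sprintf("chip_grid: %d chips (%d chromatic, %d achromatic)\n",
              nrow(x), sum(!x$achromatic), sum(x$achromatic)))
  if (any(!x$achromatic))
    cat(sprintf("  chromatic sheet: %d rows x %d hue columns\n",
                length(unique(x$row[!x$achromatic])),
                max(x$col)))
  invisible(x)
}

# CIELAB coordinate matrix of a grid (N x 3)
lab_coords <- function(grid) {
  as.matrix(grid[, c("L", "a", "b")])
}

#' Read chip CIELAB coordinates
#'
#' Two table dialects are supported.  The `"simple"` dialect is a CSV with a
#' header `id,row,col,L,a,b` (hue column 0 marks achromatic chips).  The
#' `"wcs"` dialect is the whitespace-delimited chart file distributed with
#' the World Color Survey: one row per chip carrying the chip number, a
#' lightness-value letter (A-J), the hue column (0-40), and the L*, a*, b*
#' coordinates; the column layout is declarable via `wcs_cols` and defaults
#' to the canonical chart file (9 columns, coordinates in columns 7-9).
#'
#' @param path path to the coordinate table.
#' @param dialect `"simple"` or `"wcs"`.
#' @param wcs_cols named integer vector declaring, for the wcs dialect, which
#'   columns hold `id`, `value` (the letter code), `hue`, `L`, `a`, `b`.
#' @return a [chip_grid()].
#' @export
read_chip_coordinates <- function(path,
                                  dialect = c("simple", "wcs"),
                                  wcs_cols = c(id = 1, value = 2, hue = 3,
                                               L = 7, a = 8, b = 9)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    cp_stop(sprintf("file not found: %s", path), "colorpart_io_error")
  if (dialect == "simple") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "row", "col", "L", "a", "b")
    if (!all(need %in% names(d)))
      cp_stop("simple dialect requires header id,row,col,L,a,b",
              "colorpart_format_error")
    for (cc in c("id", "row", "col", "L", "a", "b"))
      if (!is.numeric(d[[cc]]))
        cp_stop(sprintf("non-numeric column '%s'", cc),
                "colorpart_format_error")
    return(chip_grid(d$id, d$row, d$col, d$L, d$a, d$b))
  }
  # wcs dialect: whitespace-delimited, possible header line
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#", skip = 0, fill = TRUE)
  # drop a header line if the id column is not numeric there
  if (is.character(d[[wcs_cols[["id"]]]]) &&
      suppressWarnings(is.na(as.numeric(d[1, wcs_cols[["id"]]])))) {
    d <- d[-1, , drop = FALSE]
  }
  ids <- suppressWarnings(as.numeric(d[[wcs_cols[["id"]]]]))
  val <- as.character(d[[wcs_cols[["value"]]]])
  hue <- suppressWarnings(as.numeric(d[[wcs_cols[["hue"]]]]))
  Lab <- lapply(c("L", "a", "b"), function(k)
    suppressWarnings(as.numeric(d[[wcs_cols[[k]]]])))
  if (any(is.na(ids)) || any(is.na(hue)) || any(vapply(Lab, anyNA, TRUE)))
    cp_stop("non-numeric value in wcs coordinate table",
            "colorpart_format_error")
  # letter value codes A..J -> integer rows 0..9
  rows <- match(toupper(val), LETTERS[1:10]) - 1L
  if (anyNA(rows)) {
    rows2 <- suppressWarnings(as.integer(val))
    if (anyNA(rows2))
      cp_stop("unrecognized lightness-value code in wcs table",
              "colorpart_format_error")
    rows <- rows2
  }
  if (length(ids) != 330L)
    warning(sprintf("wcs dialect expects 330 chips, got %d", length(ids)))
  chip_grid(ids, rows, hue, Lab[[1]], Lab[[2]], Lab[[3]])
}

#' Write a chip grid in the simple dialect
#'
#' @param grid a [chip_grid()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chip_coordinates <- function(grid, path) {
  utils::write.csv(grid[, c("id", "row", "col", "L", "a", "b")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
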
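#' CIELAB distance between two colors
#'
#' Plain Euclidean distance in CIELAB coordinates, the standard proxy for
#' perceived color difference at the scale of a Munsell chart.
#'
#' @param c1,c2 numeric length-3 CIELAB triples `(L, a, b)`.
#' @return non-negative distance.
#' @export
cielab_distance <- function(c1, c2) {
  if (length(c1) != 3L || length(c2) != 3L ||
      any(!is.finite(c1)) || any(!is.finite(c2)))
    cp_stop("CIELAB triples must be finite length-3 vectors",
            "colorpart_domain_error")
  sqrt(sum((c1 - c2)^2))
}

#' Similarity kernel
#'
#' Perceptual similarity of two chips at CIELAB distance `d`:
#' `exp(-0.001 * d^2)`.  The scale constant 0.001 is the conventional choice
#' for this palette; it is exposed for sensitivity analysis but not varied
#' anywhere in the package's own analyses.
#'
#' @param d non-negative distance(s).
#' @param c kernel scale constant (default 0.001).
#' @return similarity in `(0, 1]`.
#' @export
similarity <- function(d, c = 0.001) {
  if (any(!is.finite(d)) || any(d < 0))
    cp_stop("distance must be finite and non-negative",
            "colorpart_domain_error")
  exp(-c * d^2)
}

#' Pairwise similarity matrix of a chip grid
#'
#' @param grid a [chip_grid()].
#' @param c kernel scale constant passed to [similarity()].
#' @return an N x N symmetric matrix of class `similarity_matrix` with unit
#'   diagonal; attribute `grid_ref` records the grid size.
#' @export
similarity_matrix <- function(grid, c = 0.001) {
  X <- lab_coords(grid)
  d2 <- as.matrix(stats::dist(X))^2
  S <- exp(-c * d2)
  diag(S) <- 1
  structure(S, grid_ref = nrow(grid),
            class = c("similarity_matrix", class(S)))
}

check_partition_matches <- function(p, sm) {
  if (length(p) != nrow(sm))
    cp_stop("partition does not cover the grid behind the similarity matrix",
            "colorpart_domain_error")
}

#' Well-formedness of a partition
#'
#' The objective `W = wS * S + wD * D`, where `S` sums the similarities of
#' all unordered within-category chip pairs and `D` sums the
#' dissimilarities `1 - sim` of all unordered between-category pairs.  With
#' the default unit weights, `W(P) <= N(N-1)/2` for any partition of N
#' chips, and W is invariant under relabeling of categories.
#'
#' @param p a [chip_partition()] (or naming system / label vector).
#' @param sm a [similarity_matrix()].
#' @param weights length-2 numeric `(wS, wD)`, default `c(1, 1)`.
#' @return an object of class `wf_score`: list with elements `S`, `D`, `W`,
#'   `n` (declared categories) and `weights`.
#' @export
wellformedness <- function(p, sm, weights = c(1, 1)) {
  p <- as_partition(p)
  check_partition_matches(p, sm)
  comp <- wf_components_cpp(unclass(sm), as.integer(p))
  S <- comp$within_sum
  D <- comp$n_between - comp$between_sum
  res <- list(S = S, D = D, W = weights[1] * S + weights[2] * D,
              n = n_categories(p), weights = as.numeric(weights))
  class(res) <- "wf_score"
  res
}

#' @export
print.wf_score <- function(x, ...) {
  cat(sprintf("W = %.4f  (S = %.4f, D = %.4f, n = %d)\n",
              x$W, x$S, x$D, x$n))
  invisible(x)
}

#' Serialize a well-formedness score to JSON
#'
#' @param x a `wf_score`.
#' @return a JSON string `{S, D, W, n, weights}`.
#' @export
wf_score_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' W values of many labelings at once
#'
#' Vectorized evaluation for ensembles and rotation scans.
#'
#' @param labmat integer matrix, one labeling per column.
#' @param sm a [similarity_matrix()].
#' @param weights length-2 numeric `(wS, wD)`.
#' @return numeric vector of W values, one per column.
#' @export
wellformedness_batch <- function(labmat, sm, weights = c(1, 1)) {
  labmat <- as.matrix(labmat)
  storage.mode(labmat) <- "integer"
  if (nrow(labmat) != nrow(sm))
    cp_stop("labeling rows must match the similarity matrix",
            "colorpart_domain_error")
  w_batch_cpp(unclass(sm), labmat, weights[1], weights[2])
}

#' Incremental W change of a single chip move
#'
#' Returns `W(p with chip moved to new_label) - W(p)`, computed in O(N)
#' from the chip's row of the similarity matrix; exactly equals the
#' difference of two full [wellformedness()] evaluations.
#'
#' @param p a [chip_partition()].
#' @param chip chip id.
#' @param new_label target label in `1..n`.
#' @param sm a [similarity_matrix()].
#' @param weights length-2 numeric `(wS, wD)`.
#' @return the W difference (0 for a no-op move).
#' @export
delta_w <- function(p, chip, new_label, sm, weights = c(1, 1)) {
  p <- as_partition(p)
  check_partition_matches(p, sm)
  k <- n_categories(p)
  if (new_label < 1L || new_label > k)
    cp_stop("new_label out of range", "colorpart_domain_error")
  if (chip < 1L || chip > length(p))
    cp_stop("chip id out of range", "colorpart_domain_error")
  delta_w_cpp(unclass(sm), as.integer(p), as.integer(chip) - 1L,
              as.integer(new_label), k, weights[1], weights[2])
}
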
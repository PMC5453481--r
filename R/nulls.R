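#' Ensemble of random Voronoi clusterings
#'
#' Each clustering is formed by sampling `n` points uniformly in the
#' axis-aligned CIELAB bounding box of the grid's chips and assigning every
#' chip to its nearest point (ties to the lowest point index).  Cells that
#' capture no chip are kept as empty categories, so the effective cluster
#' count of a draw may fall below `n`.
#'
#' @param grid a [chip_grid()].
#' @param n clusters per draw.
#' @param size ensemble size (default 1000).
#' @param seed integer seed; the ensemble is reproducible from it.
#' @return an object of class `voronoi_ensemble`: list with `partitions`
#'   (list of [chip_partition()]), `n`, `size`, `seed`, `bounds`, and
#'   `effective_n` (non-empty cells per draw).
#' @export
random_voronoi_ensemble <- function(grid, n, size = 1000L, seed = 1L) {
  if (size < 1L) cp_stop("size must be >= 1", "colorpart_domain_error")
  if (n < 1L) cp_stop("n must be >= 1", "colorpart_domain_error")
  coords <- lab_coords(grid)
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  set.seed(derive_seed(seed, "voronoi_ensemble"))
  parts <- vector("list", size)
  eff <- integer(size)
  for (i in seq_len(size)) {
    pts <- matrix(runif(3L * n, rep(lo, each = n), rep(hi, each = n)), n)
    lab <- nearest_assign_cpp(coords, pts)
    parts[[i]] <- chip_partition(lab, n)
    eff[i] <- length(unique(lab))
  }
  structure(list(partitions = parts, n = as.integer(n),
                 size = as.integer(size), seed = seed,
                 bounds = rbind(lower = lo, upper = hi),
                 effective_n = eff),
            class = "voronoi_ensemble")
}

#' @export
print.voronoi_ensemble <- function(x, ...) {
  cat(sprintf("voronoi_ensemble: %d draws of n = %d (mean effective n %.2f)\n",
              x$size, x$n, mean(x$effective_n)))
  invisible(x)
}

index_value <- function(index, a, b) {
  t <- contingency(a, b)
  switch(index, nmi = nmi(t), vi = vi(t), sj = split_join(t), ari = ari(t),
         jaccard = jaccard_pairs(t), fm = fowlkes_mallows(t))
}

#' How many random clusterings beat the reference?
#'
#' Counts the ensemble members that a solution partition represents
#' strictly better (on one index) than it represents the reference naming
#' system: for NMI/ARI/Jaccard/FM "better" means a higher index value, for
#' VI/SJ a lower one.  Ties do not count.
#'
#' @param solution a [chip_partition()] (e.g. a W-optimal solution).
#' @param reference a [naming_system()] or partition.
#' @param ensemble a [random_voronoi_ensemble()].
#' @param index one of `"nmi"`, `"vi"`, `"sj"`, `"ari"`, `"jaccard"`, `"fm"`.
#' @return an integer count in `[0, size]`.
#' @export
better_represented_count <- function(solution, reference, ensemble,
                                     index = c("nmi", "vi", "sj", "ari",
                                               "jaccard", "fm")) {
  index <- match.arg(index)
  if (length(ensemble$partitions) == 0L)
    cp_stop("empty ensemble", "colorpart_domain_error")
  ref_val <- index_value(index, solution, reference)
  vals <- vapply(ensemble$partitions,
                 function(e) index_value(index, solution, e), numeric(1))
  higher_better <- index %in% c("nmi", "ari", "jaccard", "fm")
  as.integer(if (higher_better) sum(vals > ref_val) else sum(vals < ref_val))
}

# (row, col) -> chip id lookup for the full rectangular chromatic block
chromatic_block <- function(grid) {
  chrom <- grid[!grid$achromatic, ]
  if (nrow(chrom) == 0L)
    cp_stop("rotation requires a full rectangular chromatic block",
            "colorpart_domain_error")
  rows <- sort(unique(chrom$row))
  C <- max(chrom$col)
  if (nrow(chrom) != length(rows) * C ||
      !all(table(chrom$row, chrom$col) == 1L))
    cp_stop("rotation requires a full rectangular chromatic block",
            "colorpart_domain_error")
  idx <- matrix(NA_integer_, length(rows), C)
  idx[cbind(match(chrom$row, rows), chrom$col)] <- chrom$id
  list(idx = idx, rows = rows, C = C)
}

#' Rotate a naming system along the hue dimension
#'
#' Shifts the term assignments of the chromatic chips `k` columns along the
#' cyclic hue dimension (the term at column `c` moves to column
#' `((c - 1 + k) mod C) + 1` of the same row); achromatic chips keep their
#' terms.  Rotation by 0 is the identity, and rotations compose modulo the
#' column count.
#'
#' @param ns a [naming_system()].
#' @param grid the underlying [chip_grid()]; its chromatic chips must form
#'   a full rectangular row-by-column block.
#' @param k rotation offset, `0 <= k < C`.
#' @return the rotated [naming_system()].
#' @export
rotate_naming <- function(ns, grid, k) {
  blk <- chromatic_block(grid)
  C <- blk$C
  k <- as.integer(k) %% C
  terms <- unclass(ns)
  out <- terms
  dest <- ((seq_len(C) - 1L + k) %% C) + 1L
  for (r in seq_len(nrow(blk$idx)))
    out[blk$idx[r, dest]] <- terms[blk$idx[r, ]]
  naming_system(out, language = attr(ns, "language"))
}

#' W profile over all hue rotations of a naming system
#'
#' Computes W of the partition induced by every rotation offset
#' `0 .. C-1`.  If a language's category boundaries track the bumps and
#' depressions of the chip set in CIELAB space, offset 0 should score
#' highest.
#'
#' @param ns a [naming_system()].
#' @param grid the underlying [chip_grid()].
#' @param sm a [similarity_matrix()] of the grid.
#' @param weights `(wS, wD)` weights for W.
#' @return an object of class `rotation_profile`: list with `w_values`
#'   (length C, offset 0 first) and `argmax_offset` (ties to the lowest
#'   offset).
#' @export
rotation_profile <- function(ns, grid, sm, weights = c(1, 1)) {
  C <- chromatic_block(grid)$C
  labmat <- vapply(seq_len(C) - 1L, function(k)
    as.integer(as_partition(rotate_naming(ns, grid, k))), integer(nrow(grid)))
  w <- wellformedness_batch(labmat, sm, weights)
  structure(list(w_values = w, argmax_offset = which.max(w) - 1L),
            class = "rotation_profile")
}

#' @export
print.rotation_profile <- function(x, ...) {
  n_above <- sum(x$w_values > x$w_values[1])
  cat(sprintf("rotation_profile: %d offsets, argmax %d, %d offsets above unrotated\n",
              length(x$w_values), x$argmax_offset, n_above))
  invisible(x)
}

#' How many random clusterings have a higher W than a naming system?
#'
#' @param ns a [naming_system()] (or partition).
#' @param ensemble a [random_voronoi_ensemble()] over the same grid.
#' @param sm a [similarity_matrix()] of the grid.
#' @param weights `(wS, wD)` weights for W.
#' @return an integer count of ensemble members with strictly greater W.
#' @export
w_vs_random_count <- function(ns, ensemble, sm, weights = c(1, 1)) {
  w_ref <- wellformedness(as_partition(ns), sm, weights)$W
  labmat <- vapply(ensemble$partitions, as.integer,
                   integer(nrow(sm)))
  w_ens <- wellformedness_batch(labmat, sm, weights)
  as.integer(sum(w_ens > w_ref))
}

#' Page's trend test for ordered alternatives
#'
#' Given `m` replicated rows observed under `k` ordered conditions
#' (columns), tests the null of no ordering against a monotone trend.
#' Within each row the observations are ranked (mid-ranks for ties) and the
#' statistic `L = sum_j j * R_j` formed from the column rank sums `R_j`.
#' The p-value uses the large-sample normal approximation of L with a
#' continuity correction, one-sided in the hypothesized direction.
#'
#' @param counts numeric matrix, `m` rows by `k >= 3` ordered columns.
#' @param direction `"increasing"` (default) or `"decreasing"` trend across
#'   columns left to right.
#' @return an object of class `page_test`: list with `L`, `p`, `ranks`
#'   (the within-row rank matrix actually used), `EL`, `VL`.
#' @export
pages_trend_test <- function(counts, direction = c("increasing",
                                                   "decreasing")) {
  direction <- match.arg(direction)
  counts <- as.matrix(counts)
  m <- nrow(counts); k <- ncol(counts)
  if (k < 3L) cp_stop("Page's test needs k >= 3 columns",
                      "colorpart_domain_error")
  if (direction == "decreasing") counts <- counts[, k:1, drop = FALSE]
  ranks <- t(apply(counts, 1, rank))
  Rj <- colSums(ranks)
  L <- sum(seq_len(k) * Rj)
  EL <- m * k * (k + 1)^2 / 4
  VL <- m * k^2 * (k + 1) * (k^2 - 1) / 144
  z <- (L - EL - 0.5) / sqrt(VL)
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(L = L, p = p, ranks = ranks, EL = EL, VL = VL,
                 direction = direction),
            class = "page_test")
}

#' @export
print.page_test <- function(x, ...) {
  cat(sprintf("Page's test: L = %g, p = %.4g (%s trend)\n",
              x$L, x$p, x$direction))
  invisible(x)
}
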
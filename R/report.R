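#' Representative chip of a category
#'
#' A category is displayed with the color of the chip that, among *all*
#' chips of the grid (not only the category's members), lies nearest (in
#' CIELAB) to the category centroid, where the centroid is the
#' coordinate-wise mean of the member chips' CIELAB triples.  Ties go to
#' the lowest chip id.
#'
#' @param p a [chip_partition()].
#' @param cat category label.
#' @param grid the underlying [chip_grid()].
#' @return the representative chip id.
#' @export
category_color <- function(p, cat, grid) {
  p <- as_partition(p)
  members <- which(unclass(p) == cat)
  if (!length(members))
    cp_stop("empty category has no representative color",
            "colorpart_domain_error")
  coords <- lab_coords(grid)
  centroid <- colMeans(coords[members, , drop = FALSE])
  d2 <- rowSums((coords - rep(centroid, each = nrow(coords)))^2)
  which.min(d2)   # lowest index on ties
}

# hex sRGB of chip ids (clipped into gamut)
chip_hex <- function(grid, ids) {
  lab <- lab_coords(grid)[ids, , drop = FALSE]
  rgb_ <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  rgb_ <- pmin(pmax(rgb_, 0), 1)
  grDevices::rgb(rgb_[, 1], rgb_[, 2], rgb_[, 3])
}

#' Render a naming system or partition as a chart
#'
#' Text mode returns a character matrix shaped like the chip chart (rows =
#' lightness rows, columns = achromatic column 0 followed by the hue
#' columns), one glyph per category; glyphs are assigned by descending
#' category size so diffs are stable.  Image mode additionally draws the
#' chart with [graphics::rect()], coloring every category with its
#' [category_color()] chip, and returns the glyph matrix invisibly.
#'
#' @param x a [naming_system()] or [chip_partition()].
#' @param grid the underlying [chip_grid()]; must be chart-shaped.
#' @param mode `"text"` or `"image"`.
#' @return character matrix of glyphs (invisibly for `mode = "image"`).
#' @export
render_mode_map <- function(x, grid, mode = c("text", "image")) {
  mode <- match.arg(mode)
  p <- as_partition(x)
  blk <- chromatic_block(grid)
  sizes <- tabulate(unclass(p), n_categories(p))
  glyph_pool <- c(LETTERS, letters, as.character(0:9))
  glyphs <- character(n_categories(p))
  glyphs[order(sizes, decreasing = TRUE)] <-
    glyph_pool[seq_len(n_categories(p))]
  nr <- nrow(blk$idx); C <- blk$C
  out <- matrix(" ", nr, C + 1L,
                dimnames = list(row = blk$rows, col = 0:C))
  achro <- grid$id[grid$achromatic]
  for (id in achro) {
    r <- match(grid$row[id], blk$rows)
    if (!is.na(r)) out[r, 1L] <- glyphs[p[id]]
  }
  out[, -1L] <- glyphs[unclass(p)[blk$idx]]
  if (mode == "image") {
    reps <- vapply(seq_len(n_categories(p)), function(k)
      if (sizes[k] > 0) category_color(p, k, grid) else NA_integer_,
      integer(1))
    cols <- rep(NA_character_, n_categories(p))
    cols[!is.na(reps)] <- chip_hex(grid, reps[!is.na(reps)])
    graphics::plot(NULL, xlim = c(-0.5, C + 0.5), ylim = c(nr + 0.5, 0.5),
                   xlab = "hue column (0 = achromatic)",
                   ylab = "lightness row", axes = FALSE, asp = 1)
    graphics::axis(1, at = c(0, seq(5, C, by = 5)))
    graphics::axis(2, at = seq_len(nr), labels = blk$rows, las = 1)
    for (r in seq_len(nr)) for (cc in 0:C) {
      g <- out[r, cc + 1L]
      if (g != " ")
        graphics::rect(cc - 0.5, r - 0.5, cc + 0.5, r + 0.5,
                       col = cols[match(g, glyphs)], border = NA)
    }
    return(invisible(out))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study end to end on a grid and optional reference
#' naming systems: W-optimization for a range of category counts by PSO,
#' greedy reassignment and the k-medoids baseline (a Table-1-style
#' summary), comparison of each solution with the references by all six
#' indices, random-Voronoi baselines (better-represented counts and
#' W-vs-random counts), rotation profiles of the references, and --- when
#' several category counts are scanned --- Page's trend test on the
#' better-represented counts.  All stochastic stages derive their streams
#' from `config$seed`.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{grid}{a [chip_grid()], or `NULL` to use `synth_grid()`.}
#'     \item{references}{named list of [naming_system()] objects (may be
#'       empty).}
#'     \item{n_values}{integer vector of category counts (default 3:6).}
#'     \item{seed}{integer master seed.}
#'     \item{pso_starts, pso_iterations, greedy_restarts, pam_starts}{
#'       optimizer effort.}
#'     \item{ensemble_size}{random-Voronoi draws per n (default 1000).}
#'     \item{weights}{`(wS, wD)` for W.}
#'   }
#' @param out_dir optional directory; when given, CSV/JSON artifacts
#'   (W table, comparison table, counts, rotation profiles, config echo)
#'   are written there.
#' @return list of class `colorpart_pipeline` with elements `w_table`,
#'   `solutions`, `comparisons`, `better_counts`, `w_vs_random`,
#'   `rotation`, `trend`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    grid = NULL, references = list(), n_values = 3:6, seed = 1L,
    pso_starts = 10L, pso_iterations = 250L, greedy_restarts = 20L,
    pam_starts = 100L, ensemble_size = 1000L, weights = c(1, 1)),
    config)
  grid <- if (is.null(cfg$grid)) synth_grid(synth_grid_spec(seed = cfg$seed))
          else cfg$grid
  sm <- similarity_matrix(grid)
  cfg_echo <- cfg[setdiff(names(cfg), c("grid", "references"))]
  cfg_json <- jsonlite::toJSON(cfg_echo, auto_unbox = TRUE, digits = NA)
  stamp <- cp_hash(as.character(cfg_json))

  solutions <- list(); w_rows <- list()
  for (n in cfg$n_values) {
    key <- as.character(n)
    pso <- pso_optimize(grid, n, n_starts = cfg$pso_starts,
                        iterations = cfg$pso_iterations,
                        seed = derive_seed(cfg$seed, "pipeline_pso", n),
                        weights = cfg$weights, sm = sm)
    grd <- greedy_reassign(grid, n, restarts = cfg$greedy_restarts,
                           seed = derive_seed(cfg$seed, "pipeline_greedy", n),
                           weights = cfg$weights, sm = sm)
    pam <- kmedoids_baseline(grid, n, n_starts = cfg$pam_starts,
                             seed = derive_seed(cfg$seed, "pipeline_pam", n),
                             weights = cfg$weights, sm = sm)
    solutions[[key]] <- list(pso = pso, greedy = grd, kmedoids = pam)
    w_rows[[key]] <- data.frame(n = n, W_pso = pso$score$W,
                                W_greedy = grd$score$W,
                                W_pam = pam$score$W)
  }
  w_table <- do.call(rbind, w_rows)
  rownames(w_table) <- NULL

  comparisons <- list(); better_counts <- list(); w_vs_random <- list()
  rotation <- list()
  indices <- c("nmi", "vi", "sj", "ari", "jaccard", "fm")
  for (ref_name in names(cfg$references)) {
    ref <- cfg$references[[ref_name]]
    k_ref <- n_categories(as_partition(ref))
    rotation[[ref_name]] <- rotation_profile(ref, grid, sm, cfg$weights)
    for (n in cfg$n_values) {
      key <- as.character(n)
      sol <- solutions[[key]]$pso$partition
      comparisons[[paste(ref_name, key, sep = "_n")]] <-
        compare_all(sol, ref)
      ens <- random_voronoi_ensemble(grid, n, size = cfg$ensemble_size,
                                     seed = derive_seed(cfg$seed,
                                                        "pipeline_ens", n))
      better_counts[[paste(ref_name, key, sep = "_n")]] <-
        setNames(vapply(indices, function(ix)
          better_represented_count(sol, ref, ens, ix), integer(1)), indices)
      if (n == k_ref)
        w_vs_random[[ref_name]] <- w_vs_random_count(ref, ens, sm,
                                                     cfg$weights)
    }
  }
  trend <- NULL
  if (length(better_counts) && length(cfg$n_values) >= 3L) {
    # replicated rows = (reference, index); ordered columns = n
    bymat <- do.call(rbind, lapply(names(cfg$references), function(ref_name)
      vapply(cfg$n_values, function(n)
        better_counts[[paste(ref_name, n, sep = "_n")]],
        setNames(integer(length(indices)), indices))))
    trend <- pages_trend_test(bymat, "increasing")
  }

  res <- list(w_table = w_table, solutions = solutions,
              comparisons = comparisons, better_counts = better_counts,
              w_vs_random = w_vs_random, rotation = rotation,
              trend = trend,
              config = c(cfg_echo, list(hash = stamp)))
  class(res) <- "colorpart_pipeline"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(w_table, config_hash = stamp),
                     file.path(out_dir, "w_table.csv"), row.names = FALSE)
    if (length(better_counts)) {
      bc <- data.frame(case = names(better_counts),
                       do.call(rbind, better_counts),
                       config_hash = stamp)
      utils::write.csv(bc, file.path(out_dir, "better_counts.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(config = cfg_echo, hash = stamp,
           w_vs_random = w_vs_random,
           rotation_argmax = lapply(rotation, `[[`, "argmax_offset"),
           trend = if (!is.null(trend)) list(L = trend$L, p = trend$p)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.colorpart_pipeline <- function(x, ...) {
  cat("colorpart pipeline run (config", x$config$hash, ")\n")
  print(x$w_table)
  if (!is.null(x$trend)) print(x$trend)
  invisible(x)
}
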
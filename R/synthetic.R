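#' Specification for a synthetic Munsell-like chip grid
#'
#' Defaults emulate the scale and gross shape of the canonical survey
#' palette: an 8-row by 40-column chromatic sheet plus 10 achromatic
#' chips, lightness spanning 20-90, base chroma 35, with chroma "bumps" at
#' the red and yellow hue angles (the saturated protrusions of the real
#' chip set in CIELAB) and correspondingly shallower green/blue regions.
#'
#' @param n_rows,n_cols,n_achromatic sheet dimensions.
#' @param lightness_range `(L_min, L_max)` of the chromatic rows.
#' @param chroma_base baseline chroma (radius in the a*-b* plane).
#' @param bump_amplitudes data frame with columns `hue_center_deg`,
#'   `amplitude`, `width_deg`: Gaussian chroma bumps on the hue circle.
#' @param noise_sd sd of isotropic Gaussian coordinate jitter.
#' @param seed integer seed.
#' @return a list of class `synth_grid_spec`.
#' @export
synth_grid_spec <- function(n_rows = 8L, n_cols = 40L, n_achromatic = 10L,
                            lightness_range = c(20, 90), chroma_base = 35,
                            bump_amplitudes = data.frame(
                              hue_center_deg = c(30, 90),
                              amplitude = c(25, 20),
                              width_deg = c(35, 30)),
                            noise_sd = 1.5, seed = 1L) {
  if (n_cols < 3L) cp_stop("n_cols must be >= 3", "colorpart_spec_error")
  if (any(bump_amplitudes$amplitude < 0))
    cp_stop("bump amplitudes must be non-negative", "colorpart_spec_error")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_achromatic = as.integer(n_achromatic),
                 lightness_range = lightness_range,
                 chroma_base = chroma_base,
                 bump_amplitudes = bump_amplitudes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_grid_spec")
}

# chroma as a function of hue angle (degrees) under a spec
synth_chroma <- function(theta_deg, spec) {
  ch <- rep(spec$chroma_base, length(theta_deg))
  for (i in seq_len(nrow(spec$bump_amplitudes))) {
    b <- spec$bump_amplitudes[i, ]
    d <- abs(theta_deg - b$hue_center_deg) %% 360
    d <- pmin(d, 360 - d)
    ch <- ch + b$amplitude * exp(-(d / b$width_deg)^2)
  }
  ch
}

#' Generate a synthetic Munsell-like chip grid
#'
#' The chromatic chip at row `r`, column `c` gets lightness linear in `r`
#' (top row lightest), hue angle `2 pi (c - 1) / n_cols`, and chroma
#' `chroma_base` plus the Gaussian bump contributions, so that
#' `a* = chroma cos(theta)`, `b* = chroma sin(theta)`; independent Gaussian
#' jitter of sd `noise_sd` is added to all three coordinates.  Achromatic
#' chips sit on the L* axis at evenly spaced lightness levels.  The result
#' is a pure function of the spec (including its seed).
#'
#' @param spec a [synth_grid_spec()].
#' @return a [chip_grid()] with the chromatic chips first (row-major),
#'   achromatic chips last.
#' @export
synth_grid <- function(spec = synth_grid_spec()) {
  if (any(synth_chroma(seq(0, 359.5, by = 0.5), spec) <= 0))
    cp_stop("chroma must stay positive on the whole hue circle",
            "colorpart_spec_error")
  set.seed(derive_seed(spec$seed, "synth_grid"))
  nr <- spec$n_rows; nc <- spec$n_cols; na_ <- spec$n_achromatic
  rows <- rep(seq_len(nr) - 1L, each = nc)
  cols <- rep(seq_len(nc), nr)
  Lr <- seq(spec$lightness_range[2], spec$lightness_range[1],
            length.out = nr)[rows + 1L]
  theta <- 2 * pi * (cols - 1L) / nc
  chroma <- synth_chroma(theta * 180 / pi, spec)
  L <- Lr + rnorm(nr * nc, sd = spec$noise_sd)
  a <- chroma * cos(theta) + rnorm(nr * nc, sd = spec$noise_sd)
  b <- chroma * sin(theta) + rnorm(nr * nc, sd = spec$noise_sd)
  if (na_ > 0L) {
    La <- seq(spec$lightness_range[1], spec$lightness_range[2],
              length.out = na_) + rnorm(na_, sd = spec$noise_sd)
    L <- c(L, La); a <- c(a, rnorm(na_, sd = spec$noise_sd))
    b <- c(b, rnorm(na_, sd = spec$noise_sd))
    rows <- c(rows, seq_len(na_) - 1L)
    cols <- c(cols, rep(0L, na_))
  }
  chip_grid(seq_along(L), rows, cols, L, a, b)
}

#' Generate a grid of well-separated planted blobs
#'
#' A benchmark grid for optimizer-recovery tests: `k` tight Gaussian blobs
#' of chips in CIELAB space whose centers are at least
#' `separation * spread` apart, so the planted blob membership is the
#' unambiguous W-optimal partition for `n = k`.  Because the similarity
#' kernel is wide (sim = 0.5 at distance ~26), the defaults place blob
#' centers at least 80 CIELAB units apart (separation ratio 40 with spread
#' 2), where between-blob similarity is below 0.002; centers are drawn in
#' the CIELAB-scale box `L in [0, 100]`, `a, b in [-100, 100]`.
#'
#' @param k number of blobs.
#' @param chips_per_blob chips in each blob.
#' @param spread within-blob coordinate sd.
#' @param separation minimum center separation in units of `spread`.
#' @param seed integer seed.
#' @return list with `grid` (a [chip_grid()]; all chips marked achromatic
#'   as the blob layout has no hue chart), `truth` (the planted
#'   [chip_partition()]) and `centers` (the `k x 3` blob centers).
#' @export
synth_blob_grid <- function(k, chips_per_blob = 30L, spread = 2,
                            separation = 40, seed = 1L) {
  set.seed(derive_seed(seed, "blob_grid"))
  min_d <- separation * spread
  draw <- function() c(runif(1, 0, 100), runif(2, -100, 100))
  centers <- matrix(draw(), 1)
  tries <- 0L
  while (nrow(centers) < k) {
    cand <- draw()
    if (min(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2))) >=
        min_d)
      centers <- rbind(centers, cand)
    if ((tries <- tries + 1L) > 100000L)
      cp_stop("cannot place blob centers at the requested separation",
              "colorpart_spec_error")
  }
  N <- k * chips_per_blob
  lab <- rep(seq_len(k), each = chips_per_blob)
  X <- centers[lab, ] + matrix(rnorm(3 * N, sd = spread), N)
  g <- chip_grid(seq_len(N), rep(0L, N), rep(0L, N), X[, 1], X[, 2], X[, 3])
  list(grid = g, truth = chip_partition(lab, k), centers = unname(centers))
}

#' Plant a Voronoi naming system on a grid
#'
#' Labels every chip by its nearest of `k` seed points, then flips each
#' chip's label to a uniformly random *other* label with probability
#' `noise_rate`.  Returns both the noisy naming system and the noise-free
#' ground truth.
#'
#' @param grid a [chip_grid()].
#' @param k number of categories.
#' @param seed_points `k x 3` matrix of CIELAB triples, or `"sample"` to
#'   draw them uniformly in the grid's bounding box.
#' @param noise_rate label-flip probability in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `naming` (a [naming_system()], terms `"t1".."tk"`)
#'   and `truth` (the noise-free [chip_partition()]).
#' @export
planted_naming <- function(grid, k, seed_points = "sample", noise_rate = 0,
                           seed = 1L) {
  N <- nrow(grid)
  if (k > N) cp_stop("k exceeds the number of chips",
                     "colorpart_domain_error")
  if (noise_rate < 0 || noise_rate >= 1)
    cp_stop("noise_rate must be in [0, 1)", "colorpart_domain_error")
  set.seed(derive_seed(seed, "planted_naming"))
  coords <- lab_coords(grid)
  if (identical(seed_points, "sample")) {
    lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
    seed_points <- matrix(runif(3L * k, rep(lo, each = k),
                                rep(hi, each = k)), k)
  }
  truth <- nearest_assign_cpp(coords, as.matrix(seed_points))
  noisy <- truth
  if (noise_rate > 0 && k > 1L) {
    flip <- runif(N) < noise_rate
    if (any(flip)) {
      shift <- sample.int(k - 1L, sum(flip), replace = TRUE)
      noisy[flip] <- ((truth[flip] - 1L + shift) %% k) + 1L
    }
  }
  list(naming = naming_system(paste0("t", noisy)),
       truth = chip_partition(truth, k))
}

#' Simulate multi-speaker naming responses
#'
#' Each of `n_speakers` repeats a naming system, corrupting every chip
#' independently with probability `disagreement` to a uniformly random
#' other term of the system.  [mode_map()] over the output recovers the
#' input with probability approaching 1 as the speaker count grows.
#'
#' @param ns a [naming_system()].
#' @param n_speakers number of speakers (>= 1).
#' @param disagreement per-chip corruption probability in `[0, 1)`.
#' @param seed integer seed.
#' @return data frame with columns `speaker`, `chip_id`, `term`.
#' @export
synth_responses <- function(ns, n_speakers, disagreement = 0, seed = 1L) {
  if (n_speakers < 1L) cp_stop("need at least one speaker",
                               "colorpart_domain_error")
  set.seed(derive_seed(seed, "synth_responses"))
  terms <- unclass(ns)
  vocab <- unique(terms)
  N <- length(terms)
  out <- vector("list", n_speakers)
  for (s in seq_len(n_speakers)) {
    resp <- terms
    if (disagreement > 0 && length(vocab) > 1L) {
      flip <- runif(N) < disagreement
      if (any(flip)) {
        cur <- match(resp[flip], vocab)
        shift <- sample.int(length(vocab) - 1L, sum(flip), replace = TRUE)
        resp[flip] <- vocab[((cur - 1L + shift) %% length(vocab)) + 1L]
      }
    }
    out[[s]] <- data.frame(speaker = s, chip_id = seq_len(N), term = resp)
  }
  do.call(rbind, out)
}
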
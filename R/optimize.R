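new_optim_result <- function(partition, sm, weights, method, n_starts,
                             best_start_index, seed, trace = NULL,
                             per_start_w = NULL, extra = list()) {
  res <- c(list(partition = partition,
                score = wellformedness(partition, sm, weights),
                n_starts = n_starts, best_start_index = best_start_index,
                seed = seed, method = method, trace = trace,
                per_start_w = per_start_w), extra)
  class(res) <- "wf_optim"
  res
}

#' @export
print.wf_optim <- function(x, ...) {
  cat(sprintf("wf_optim [%s]: n = %d, W = %.4f (best of %d starts, start %d)\n",
              x$method, x$score$n, x$score$W, x$n_starts, x$best_start_index))
  invisible(x)
}

#' Maximize W by particle swarm optimization over category centroids
#'
#' A particle encodes `n` centroid triples in CIELAB, each coordinate
#' bounded by the per-channel min/max over the grid's chips.  A particle
#' decodes to a partition by assigning every chip to its nearest centroid
#' (Euclidean, ties to the lowest centroid index); its fitness is the W of
#' that partition.  `n_starts` independent swarm runs are performed and the
#' best decoded partition returned.  Per-start seeds are derived from
#' `seed` and the start index, so the first `k` starts of a longer run
#' coincide with a `k`-start run (doubling `n_starts` can never lower the
#' best W).
#'
#' Swarm dynamics use the constriction-style constants (inertia 0.729,
#' cognitive = social = 1.494) with absorbing bounds: a coordinate leaving
#' the box is clamped and its velocity component zeroed.
#'
#' @param grid a [chip_grid()].
#' @param n number of categories, `1 <= n <= N`.
#' @param n_starts independent swarm runs (default 100).
#' @param seed integer seed.
#' @param swarm_size particles per swarm (default 40).
#' @param iterations iterations per run (default 500).
#' @param screen_starts per run, this many extra random centroid sets are
#'   scored and the best one seeds particle 1 of the swarm (start-value
#'   screening; default 100).
#' @param inertia,cognitive,social swarm constants.
#' @param weights `(wS, wD)` weights for W.
#' @param sm optional precomputed [similarity_matrix()].
#' @param init optional numeric matrix (`n` x 3) of centroid triples used to
#'   seed one particle of every swarm (the rest are random).
#' @return a `wf_optim` result; `$trace` holds the best-so-far W per
#'   iteration of the winning start.
#' @export
pso_optimize <- function(grid, n, n_starts = 100L, seed = 1L,
                         swarm_size = 40L, iterations = 500L,
                         screen_starts = 100L,
                         inertia = 0.729, cognitive = 1.494, social = 1.494,
                         weights = c(1, 1), sm = NULL, init = NULL) {
  N <- nrow(grid)
  if (n < 1L || n > N) cp_stop("n must be in 1..N", "colorpart_domain_error")
  if (is.null(sm)) sm <- similarity_matrix(grid)
  coords <- lab_coords(grid)
  if (n == 1L) {
    p <- chip_partition(rep(1L, N), 1L)
    return(new_optim_result(p, sm, weights, "pso", n_starts, 1L, seed))
  }
  lower <- rep(apply(coords, 2, min), each = n)
  upper <- rep(apply(coords, 2, max), each = n)
  dim_ <- 3L * n
  span <- upper - lower
  best_w <- -Inf; best_par <- NULL; best_idx <- NA_integer_; best_trace <- NULL
  per_start <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(derive_seed(seed, "pso", s))
    X <- matrix(runif(swarm_size * dim_), swarm_size) *
      rep(span, each = swarm_size) + rep(lower, each = swarm_size)
    if (!is.null(init)) {
      X[1L, ] <- as.numeric(init)   # column-major: (L_1..L_n, a_1..a_n, b_1..b_n)
    } else if (screen_starts > 0L) {
      cand <- matrix(runif(screen_starts * dim_), screen_starts) *
        rep(span, each = screen_starts) + rep(lower, each = screen_starts)
      cfit <- pso_eval_batch_cpp(coords, unclass(sm), cand, n,
                                 weights[1], weights[2])
      X[1L, ] <- cand[which.max(cfit), ]
    }
    V <- (matrix(runif(swarm_size * dim_), swarm_size) - 0.5) *
      rep(span, each = swarm_size) * 0.5
    fit <- pso_eval_batch_cpp(coords, unclass(sm), X, n,
                              weights[1], weights[2])
    pbest <- X; pbest_fit <- fit
    g <- which.max(fit); gbest <- X[g, ]; gbest_fit <- fit[g]
    trace <- numeric(iterations)
    for (it in seq_len(iterations)) {
      r1 <- matrix(runif(swarm_size * dim_), swarm_size)
      r2 <- matrix(runif(swarm_size * dim_), swarm_size)
      V <- inertia * V + cognitive * r1 * (pbest - X) +
        social * r2 * (rep(gbest, each = swarm_size) - X)
      X <- X + V
      out_lo <- X < rep(lower, each = swarm_size)
      out_hi <- X > rep(upper, each = swarm_size)
      X[out_lo] <- rep(lower, each = swarm_size)[out_lo]
      X[out_hi] <- rep(upper, each = swarm_size)[out_hi]
      V[out_lo | out_hi] <- 0
      fit <- pso_eval_batch_cpp(coords, unclass(sm), X, n,
                                weights[1], weights[2])
      imp <- fit > pbest_fit
      pbest[imp, ] <- X[imp, , drop = FALSE]; pbest_fit[imp] <- fit[imp]
      g <- which.max(pbest_fit)
      if (pbest_fit[g] > gbest_fit) {
        gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
      }
      trace[it] <- gbest_fit
    }
    per_start[s] <- gbest_fit
    if (gbest_fit > best_w) {
      best_w <- gbest_fit; best_par <- gbest; best_idx <- s
      best_trace <- trace
    }
  }
  centers <- matrix(best_par, n)
  labels <- nearest_assign_cpp(coords, centers)
  p <- chip_partition(labels, n)
  new_optim_result(p, sm, weights, "pso", n_starts, best_idx, seed,
                   trace = best_trace, per_start_w = per_start,
                   extra = list(centroids = centers,
                                effective_n = length(unique(labels))))
}

#' Maximize W by greedy chip reassignment
#'
#' Per restart: chips receive uniform random initial labels in `1..n`; chips
#' are then visited in a fresh random order each sweep, each moved to the
#' label giving the greatest strictly positive W increase (staying put
#' otherwise); sweeps repeat until one makes zero moves.  The best restart
#' by W is returned.  W is non-decreasing within every restart.
#'
#' @param grid a [chip_grid()].
#' @param n number of categories.
#' @param restarts random restarts (default 20).
#' @param seed integer seed.
#' @param weights `(wS, wD)` weights for W.
#' @param sm optional precomputed [similarity_matrix()].
#' @return a `wf_optim` result; `$trace` holds the W value after each sweep
#'   of the winning restart.
#' @export
greedy_reassign <- function(grid, n, restarts = 20L, seed = 1L,
                            weights = c(1, 1), sm = NULL) {
  N <- nrow(grid)
  if (n < 1L || n > N) cp_stop("n must be in 1..N", "colorpart_domain_error")
  if (is.null(sm)) sm <- similarity_matrix(grid)
  if (n == 1L) {
    p <- chip_partition(rep(1L, N), 1L)
    return(new_optim_result(p, sm, weights, "greedy", restarts, 1L, seed))
  }
  best_w <- -Inf; best_labels <- NULL; best_idx <- NA_integer_
  best_trace <- NULL
  per_start <- numeric(restarts)
  Sm <- unclass(sm)
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, "greedy", r))
    labels <- sample.int(n, N, replace = TRUE)
    w <- wellformedness(chip_partition(labels, n), sm, weights)$W
    trace <- w
    repeat {
      ord <- sample.int(N) - 1L
      sw <- greedy_sweep_cpp(Sm, labels, n, ord, weights[1], weights[2])
      labels <- sw$labels
      w <- w + sw$gain
      trace <- c(trace, w)
      if (sw$moves == 0L) break
    }
    per_start[r] <- w
    if (w > best_w) {
      best_w <- w; best_labels <- labels; best_idx <- r; best_trace <- trace
    }
  }
  p <- chip_partition(best_labels, n)
  new_optim_result(p, sm, weights, "greedy", restarts, best_idx, seed,
                   trace = best_trace, per_start_w = per_start)
}

#' k-medoids (PAM) baseline partition
#'
#' Classic Partitioning Around Medoids on the CIELAB Euclidean distances:
#' `n` distinct chips are drawn uniformly as initial medoids and the swap
#' phase iterates to a local optimum of the total distance-to-medoid cost
#' (no build phase); the best of `n_starts` starts by PAM cost is kept.
#' PAM does not optimize W; the returned score is the W of the resulting
#' partition, reported for comparison with the W-optimizers.
#'
#' The swap phase is delegated to [cluster::pam()].
#'
#' @param grid a [chip_grid()].
#' @param n number of clusters.
#' @param n_starts random starts (default 2500).
#' @param seed integer seed.
#' @param weights `(wS, wD)` weights for the reported W.
#' @param sm optional precomputed [similarity_matrix()].
#' @return a `wf_optim` result with extra elements `medoids` (chip ids) and
#'   `pam_cost` (total distance to nearest medoid).
#' @export
kmedoids_baseline <- function(grid, n, n_starts = 2500L, seed = 1L,
                              weights = c(1, 1), sm = NULL) {
  N <- nrow(grid)
  if (n < 1L || n > N) cp_stop("n must be in 1..N", "colorpart_domain_error")
  if (is.null(sm)) sm <- similarity_matrix(grid)
  coords <- lab_coords(grid)
  if (n == N) {
    p <- chip_partition(seq_len(N), N)
    return(new_optim_result(p, sm, weights, "kmedoids", n_starts, 1L, seed,
                            extra = list(medoids = seq_len(N), pam_cost = 0)))
  }
  dx <- stats::dist(coords)
  best_cost <- Inf; best_med <- NULL; best_idx <- NA_integer_
  per_start <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(derive_seed(seed, "kmedoids", s))
    med0 <- sample.int(N, n)
    fit <- cluster::pam(dx, k = n, medoids = med0, do.swap = TRUE,
                        pamonce = 5, cluster.only = FALSE, keep.diss = FALSE)
    med <- as.integer(fit$id.med)
    d2c <- nearest_assign_cpp(coords, coords[med, , drop = FALSE])
    cost <- sum(sqrt(rowSums((coords - coords[med[d2c], , drop = FALSE])^2)))
    per_start[s] <- cost
    if (cost < best_cost) {
      best_cost <- cost; best_med <- med; best_idx <- s
    }
  }
  labels <- nearest_assign_cpp(coords, coords[best_med, , drop = FALSE])
  p <- chip_partition(labels, n)
  new_optim_result(p, sm, weights, "kmedoids", n_starts, best_idx, seed,
                   per_start_w = per_start,
                   extra = list(medoids = best_med, pam_cost = best_cost))
}
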
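# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's contingency/pair-count code paths.

# all set partitions of n items as restricted-growth label vectors
all_set_partitions <- function(n, max_blocks = n) {
  out <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return(invisible())
    }
    for (v in seq_len(min(mx + 1L, max_blocks)))
      rec(c(pref, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# pair-classification oracle: walk every unordered item pair explicitly
oracle_pair_indices <- function(a, b) {
  N <- length(a)
  TP <- FP <- FN <- TN <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) TP <- TP + 1
    else if (sa) FP <- FP + 1
    else if (sb) FN <- FN + 1
    else TN <- TN + 1
  }
  tot <- TP + FP + FN + TN
  exp_tp <- (TP + FP) * (TP + FN) / tot
  max_tp <- ((TP + FP) + (TP + FN)) / 2
  ari <- if (max_tp == exp_tp) {
    if (FP + FN == 0) 1 else 0
  } else (TP - exp_tp) / (max_tp - exp_tp)
  list(ari = ari,
       jaccard = if (TP + FP + FN == 0) 0 else TP / (TP + FP + FN),
       fm = if ((TP + FP) * (TP + FN) == 0) 0
            else TP / sqrt((TP + FP) * (TP + FN)))
}

# entropy oracle: probabilities counted by explicit subsetting
oracle_entropy_indices <- function(a, b) {
  N <- length(a)
  ent <- function(x) {
    p <- as.numeric(table(x)) / N
    -sum(p * log(p))
  }
  Ha <- ent(a); Hb <- ent(b)
  I <- 0
  for (ca in unique(a)) for (cb in unique(b)) {
    pij <- sum(a == ca & b == cb) / N
    if (pij > 0) {
      pa <- sum(a == ca) / N; pb <- sum(b == cb) / N
      I <- I + pij * log(pij / (pa * pb))
    }
  }
  nmi <- if (Ha + Hb == 0) 1 else 2 * I / (Ha + Hb)
  list(nmi = nmi, vi = max(0, Ha + Hb - 2 * I))
}

# split/join oracle: per-cluster best-match overlaps found by subsetting
oracle_sj <- function(a, b) {
  N <- length(a)
  best_a <- sum(vapply(unique(a), function(ca)
    max(vapply(unique(b), function(cb) sum(a == ca & b == cb), 0)), 0))
  best_b <- sum(vapply(unique(b), function(cb)
    max(vapply(unique(a), function(ca) sum(a == ca & b == cb), 0)), 0))
  2 * N - best_a - best_b
}

# W oracle: explicit double loop over unordered chip pairs
oracle_w <- function(labels, grid, weights = c(1, 1)) {
  X <- as.matrix(grid[, c("L", "a", "b")])
  N <- nrow(X)
  S <- 0; D <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    s <- exp(-0.001 * sum((X[i, ] - X[j, ])^2))
    if (labels[i] == labels[j]) S <- S + s else D <- D + (1 - s)
  }
  list(S = S, D = D, W = weights[1] * S + weights[2] * D)
}

# exact null distribution of Page's L for an m x k no-tie matrix:
# every row's rank vector is an independent uniform permutation of 1..k
oracle_page_exact_p <- function(counts) {
  m <- nrow(counts); k <- ncol(counts)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  pk <- perms(seq_len(k))
  row_L <- vapply(pk, function(p) sum(seq_len(k) * p), 0)
  # distribution of the sum of m independent row contributions
  dist <- setNames(rep(1 / length(row_L), length(row_L)),
                   as.character(row_L))
  conv <- function(d1, vals) {
    out <- new.env()
    for (nm in names(d1)) for (v in vals) {
      key <- as.character(as.numeric(nm) + v)
      prev <- if (is.null(out[[key]])) 0 else out[[key]]
      out[[key]] <- prev + d1[[nm]] / length(vals)
    }
    unlist(as.list(out))
  }
  d <- dist
  if (m > 1) for (r in 2:m) d <- conv(d, row_L)
  L_obs <- sum(vapply(seq_len(m), function(r)
    sum(seq_len(k) * rank(counts[r, ])), 0))
  sum(d[as.numeric(names(d)) >= L_obs])
}

# uniformly random partition labels (not necessarily surjective)
random_labels <- function(N, k) sample.int(k, N, replace = TRUE)

# small deterministic test grid
toy_grid <- function(N = 10, seed = 42) {
  set.seed(seed)
  chip_grid(seq_len(N), rep(0L, N), rep(0L, N),
            runif(N, 0, 100), runif(N, -80, 80), runif(N, -80, 80))
}
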
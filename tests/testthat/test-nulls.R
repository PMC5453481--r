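# a small chart-shaped grid shared across rotation tests
grid_sm <- synth_grid(synth_grid_spec(n_rows = 4, n_cols = 12,
                                      n_achromatic = 3, seed = 2))
sm_sm <- similarity_matrix(grid_sm)

test_that("random Voronoi ensembles are reproducible and respect bounds", {
  e1 <- random_voronoi_ensemble(grid_sm, 4, size = 50, seed = 9)
  e2 <- random_voronoi_ensemble(grid_sm, 4, size = 50, seed = 9)
  expect_identical(lapply(e1$partitions, as.integer),
                   lapply(e2$partitions, as.integer))
  expect_true(all(e1$effective_n <= 4))
  expect_true(all(vapply(e1$partitions, function(p) attr(p, "n"), 0L) == 4L))

  # n = 1: every draw is the one-cluster partition
  e <- random_voronoi_ensemble(grid_sm, 1, size = 5, seed = 1)
  expect_true(all(vapply(e$partitions,
                         function(p) all(as.integer(p) == 1L), TRUE)))
  expect_error(random_voronoi_ensemble(grid_sm, 4, size = 0, seed = 1),
               ">= 1")
})

test_that("nothing beats a perfect reference in better-represented counts", {
  set.seed(10)
  sol <- chip_partition(random_labels(nrow(grid_sm), 4), 4)
  ens <- random_voronoi_ensemble(grid_sm, 4, size = 40, seed = 3)
  for (ix in c("nmi", "vi", "sj", "ari", "jaccard", "fm"))
    expect_equal(better_represented_count(sol, sol, ens, ix), 0L)
})

test_that("a reference drawn from the ensemble process sits mid-ensemble", {
  # exchangeability: a reference drawn from the very process that generates
  # the ensemble has a uniform rank among the draws, so the count is
  # size/2 in expectation (sd size/sqrt(12) per reference); average over
  # independent references to get a tight band
  sol <- greedy_reassign(grid_sm, 4, restarts = 3, seed = 4,
                         sm = sm_sm)$partition
  ens <- random_voronoi_ensemble(grid_sm, 4, size = 60, seed = 5)
  refs <- random_voronoi_ensemble(grid_sm, 4, size = 20, seed = 77)$partitions
  cnts <- vapply(refs, function(ref)
    better_represented_count(sol, ref, ens, "ari"), integer(1))
  se <- (60 / sqrt(12)) / sqrt(length(cnts))
  expect_lt(abs(mean(cnts) - 30), 3 * se)
})

test_that("rotation is a cyclic group action fixing achromatic chips", {
  pn <- planted_naming(grid_sm, 5, seed = 6)
  ns <- pn$naming
  expect_equal(unclass(rotate_naming(ns, grid_sm, 0)), unclass(ns))
  r1 <- rotate_naming(ns, grid_sm, 5)
  r2 <- rotate_naming(r1, grid_sm, 9)
  expect_equal(unclass(r2),
               unclass(rotate_naming(ns, grid_sm, (5 + 9) %% 12)))
  # full turn is the identity
  expect_equal(unclass(rotate_naming(ns, grid_sm, 12)), unclass(ns))
  achro <- grid_sm$id[grid_sm$achromatic]
  expect_equal(as.character(r1)[achro], as.character(ns)[achro])
  # rotation refuses grids whose chromatic block has holes
  holey <- chip_grid(1:5, c(0, 0, 1, 1, 0), c(1, 2, 1, 2, 0),
                     L = 50 + 1:5, a = 1:5, b = 1:5)
  holey <- holey[-2, ]
  holey$id <- 1:4
  class(holey) <- c("chip_grid", "data.frame")
  expect_error(rotate_naming(naming_system(letters[1:4]), holey, 1),
               "rectangular")
  expect_error(rotate_naming(ns, toy_grid(6), 1), "rectangular")
})

test_that("row-banded naming systems have a flat rotation profile", {
  terms <- paste0("band", grid_sm$row + 1L)
  ns <- naming_system(terms)
  rp <- rotation_profile(ns, grid_sm, sm_sm)
  expect_length(rp$w_values, 12L)
  expect_equal(max(rp$w_values) - min(rp$w_values), 0, tolerance = 1e-6)
})

test_that("a system planted at its W-best rotation peaks at offset 0", {
  # an arbitrary Voronoi draw need not favor offset 0, but rotating any
  # system to its W-maximal offset must by the group property
  g <- synth_grid(synth_grid_spec(seed = 8))
  smg <- similarity_matrix(g)
  pn <- planted_naming(g, 6, seed = 21)
  rp <- rotation_profile(pn$naming, g, smg)
  expect_equal(rp$w_values[1], wellformedness(pn$naming, smg)$W,
               tolerance = 1e-9)
  best <- rotate_naming(pn$naming, g, rp$argmax_offset)
  rp2 <- rotation_profile(best, g, smg)
  expect_equal(rp2$argmax_offset, 0L)
  expect_equal(max(rp2$w_values), max(rp$w_values), tolerance = 1e-9)
})

test_that("W-vs-random counts honor strict comparison", {
  ens <- random_voronoi_ensemble(grid_sm, 3, size = 30, seed = 12)
  wvals <- wellformedness_batch(vapply(ens$partitions, as.integer,
                                       integer(nrow(grid_sm))), sm_sm)
  best <- ens$partitions[[which.max(wvals)]]
  expect_equal(w_vs_random_count(best, ens, sm_sm), 0L)
  worst <- ens$partitions[[which.min(wvals)]]
  expect_equal(w_vs_random_count(worst, ens, sm_sm),
               sum(wvals > min(wvals)))
})

test_that("Page's L hits its closed-form extremes on ordered toys", {
  up <- rbind(c(1, 2, 3), c(2, 4, 6))
  r <- pages_trend_test(up, "increasing")
  expect_equal(r$L, 28)                      # the maximum for m = 2, k = 3
  down <- up[, 3:1]
  r2 <- pages_trend_test(down, "increasing")
  expect_equal(r2$L, 2 * (3 + 4 + 3))        # minimum: ranks reversed
  # the decreasing direction recovers the maximum on the reversed data
  expect_equal(pages_trend_test(down, "decreasing")$L, 28)
  expect_error(pages_trend_test(up[, 1:2, drop = FALSE]), "k >= 3")
})

test_that("normal approximation tracks the exact permutation null", {
  set.seed(13)
  for (rep in 1:6) {
    counts <- matrix(sample(1:100, 12), 3, 4)   # m = 3, k = 4, no ties
    r <- pages_trend_test(counts, "increasing")
    p_exact <- oracle_page_exact_p(counts)
    expect_lt(abs(r$p - p_exact), 0.02)
  }
})
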
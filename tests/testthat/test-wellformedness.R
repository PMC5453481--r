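test_that("CIELAB distance is the Euclidean norm", {
  expect_equal(cielab_distance(c(50, 0, 0), c(50, 0, 0)), 0)
  expect_equal(cielab_distance(c(50, 0, 0), c(50, 3, 4)), 5)
  expect_equal(cielab_distance(c(0, 0, 0), c(100, 0, 0)), 100)
  expect_error(cielab_distance(c(NA, 0, 0), c(0, 0, 0)), "finite")
})

test_that("similarity kernel is exp(-0.001 d^2)", {
  expect_equal(similarity(0), 1)
  expect_equal(similarity(sqrt(1000)), exp(-1))
  expect_equal(similarity(100), exp(-10))
  expect_error(similarity(-1), "non-negative")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  g1 <- chip_grid(1L, 0L, 0L, 50, 0, 0)
  expect_equal(unclass(similarity_matrix(g1))[1, 1], 1)

  g2 <- chip_grid(1:2, c(0L, 0L), c(0L, 0L), c(50, 50), c(0, 3), c(0, 4))
  sm <- similarity_matrix(g2)
  expect_equal(sm[1, 2], exp(-0.025))
  expect_equal(sm[2, 1], sm[1, 2])

  g <- synth_grid()
  sm <- similarity_matrix(g)
  expect_equal(dim(sm), c(330L, 330L))
  expect_true(isSymmetric(unclass(sm)))
  expect_equal(unname(diag(sm)), rep(1, 330))
  expect_true(all(sm > 0 & sm <= 1))
})

test_that("two-chip W splits into S and D as expected", {
  # place the chips so that sim = 0.5 exactly: d^2 = 1000 log(2)
  d <- sqrt(1000 * log(2))
  g <- chip_grid(1:2, c(0L, 0L), c(0L, 0L), c(0, d), c(0, 0), c(0, 0))
  sm <- similarity_matrix(g)
  one <- wellformedness(chip_partition(c(1, 1), 1), sm)
  expect_equal(c(one$S, one$D, one$W), c(0.5, 0, 0.5))
  two <- wellformedness(chip_partition(c(1, 2), 2), sm)
  expect_equal(c(two$S, two$D, two$W), c(0, 0.5, 0.5))
})

test_that("W agrees with the pair-by-pair oracle on all 52 partitions of 5 chips", {
  g <- toy_grid(5)
  sm <- similarity_matrix(g)
  parts <- all_set_partitions(5)
  expect_length(parts, 52L)
  for (lab in parts) {
    p <- chip_partition(lab)
    got <- wellformedness(p, sm)
    want <- oracle_w(lab, g)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$D, want$D, tolerance = 1e-9)
    expect_equal(got$W, want$W, tolerance = 1e-9)
  }
})

test_that("W is invariant under category relabeling and bounded by the pair count", {
  g <- toy_grid(20)
  sm <- similarity_matrix(g)
  set.seed(11)
  for (rep in 1:20) {
    lab <- random_labels(20, 4)
    w1 <- wellformedness(chip_partition(lab, 4), sm)$W
    perm <- sample.int(4)
    w2 <- wellformedness(chip_partition(perm[lab], 4), sm)$W
    expect_equal(w1, w2, tolerance = 1e-12)
    expect_lte(w1, choose(20, 2))
  }
})

test_that("pair-count conservation holds: W + complementary sum = N(N-1)/2", {
  g <- toy_grid(30)
  sm <- similarity_matrix(g)
  set.seed(12)
  for (rep in 1:25) {
    lab <- random_labels(30, 5)
    p <- chip_partition(lab, 5)
    w <- wellformedness(p, sm)
    # complementary sum computed independently from the matrix itself
    same <- outer(lab, lab, "==")
    up <- upper.tri(sm)
    complementary <- sum((1 - sm)[same & up]) + sum(sm[!same & up])
    expect_equal(w$W + complementary, choose(30, 2), tolerance = 1e-9)
  }
})

test_that("extreme partitions have the closed-form W", {
  g <- toy_grid(15)
  sm <- similarity_matrix(g)
  total_sim <- (sum(sm) - 15) / 2
  allone <- wellformedness(chip_partition(rep(1L, 15), 1), sm)
  expect_equal(allone$W, total_sim, tolerance = 1e-9)
  singles <- wellformedness(chip_partition(1:15, 15), sm)
  expect_equal(singles$W, choose(15, 2) - total_sim, tolerance = 1e-9)
})

test_that("component weights scale S and D linearly", {
  g <- toy_grid(12)
  sm <- similarity_matrix(g)
  p <- chip_partition(random_labels(12, 3), 3)
  w11 <- wellformedness(p, sm)
  w23 <- wellformedness(p, sm, weights = c(2, 3))
  expect_equal(w23$W, 2 * w11$S + 3 * w11$D, tolerance = 1e-12)
})

test_that("delta_w matches full recomputation for arbitrary moves", {
  g <- toy_grid(20)
  sm <- similarity_matrix(g)
  set.seed(5)
  lab <- random_labels(20, 4)
  p <- chip_partition(lab, 4)
  # no-op move
  expect_equal(delta_w(p, 7, lab[7], sm), 0)
  for (rep in 1:50) {
    chip <- sample.int(20, 1)
    new_lab <- sample.int(4, 1)
    moved <- lab
    moved[chip] <- new_lab
    want <- wellformedness(chip_partition(moved, 4), sm)$W -
      wellformedness(p, sm)$W
    expect_equal(delta_w(p, chip, new_lab, sm), want, tolerance = 1e-9)
  }
  # moving the sole member of a category empties it; n stays declared
  sole <- chip_partition(c(2L, rep(1L, 19)), 4)
  moved <- chip_partition(c(3L, rep(1L, 19)), 4)
  want <- wellformedness(moved, sm)$W - wellformedness(sole, sm)$W
  expect_equal(delta_w(sole, 1, 3, sm), want, tolerance = 1e-9)
  expect_error(delta_w(p, 1, 9, sm), "out of range")
})

test_that("batch W evaluation matches scalar evaluation", {
  g <- toy_grid(25)
  sm <- similarity_matrix(g)
  set.seed(3)
  labmat <- replicate(8, random_labels(25, 5))
  wb <- wellformedness_batch(labmat, sm)
  for (j in 1:8)
    expect_equal(wb[j], wellformedness(chip_partition(labmat[, j], 5), sm)$W,
                 tolerance = 1e-9)
})

test_that("scores serialize to JSON with all components", {
  g <- toy_grid(6)
  p <- chip_partition(random_labels(6, 2), 2)
  j <- jsonlite::fromJSON(wf_score_json(wellformedness(p, similarity_matrix(g))))
  expect_named(j, c("S", "D", "W", "n", "weights"))
  expect_equal(j$W, j$S + j$D, tolerance = 1e-9)
})
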
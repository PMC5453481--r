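test_that("contingency tables count co-occurrences", {
  a <- chip_partition(c(1, 1, 1, 2, 2), 2)
  t1 <- contingency(a, a)
  expect_equal(unclass(t1)[, ], diag(c(3, 2)), ignore_attr = TRUE)

  t2 <- contingency(chip_partition(rep(1, 4), 1), chip_partition(1:4, 4))
  expect_equal(dim(t2), c(1L, 4L))
  expect_true(all(t2 == 1))

  b <- chip_partition(c(1, 2, 2, 3, 3), 3)
  perm <- c(3L, 1L, 2L)
  b2 <- chip_partition(perm[as.integer(b)], 3)
  expect_equal(unclass(contingency(a, b2))[, perm],
               unclass(contingency(a, b))[, ], ignore_attr = TRUE)

  expect_error(contingency(a, chip_partition(c(1, 2), 2)), "different chip")
})

test_that("identical clusterings score (1, 0, 0, 1, 1, 1)", {
  set.seed(21)
  a <- chip_partition(random_labels(40, 5), 5)
  rep_ <- compare_all(a, a)
  expect_equal(unlist(rep_), c(nmi = 1, vi = 0, sj = 0, ari = 1,
                               jaccard = 1, fm = 1))
  # relabeled copy is still identical as a clustering
  perm <- sample.int(5)
  b <- chip_partition(perm[as.integer(a)], 5)
  expect_equal(unlist(compare_all(a, b)),
               c(nmi = 1, vi = 0, sj = 0, ari = 1, jaccard = 1, fm = 1))
})

test_that("six-item toy pair matches the hand oracles", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 3, 3)
  t <- contingency(chip_partition(a), chip_partition(b))
  po <- oracle_pair_indices(a, b)
  eo <- oracle_entropy_indices(a, b)
  expect_equal(ari(t), po$ari, tolerance = 1e-12)
  expect_equal(jaccard_pairs(t), po$jaccard, tolerance = 1e-12)
  expect_equal(fowlkes_mallows(t), po$fm, tolerance = 1e-12)
  expect_equal(nmi(t), eo$nmi, tolerance = 1e-12)
  expect_equal(vi(t), eo$vi, tolerance = 1e-12)
  expect_equal(split_join(t), oracle_sj(a, b))
})

test_that("split/join equals the hand-enumerated toy value", {
  t <- contingency(chip_partition(c(1, 1, 2, 2)), chip_partition(c(1, 2, 1, 2)))
  # 2N - (1+1)-maxima: 8 - 2 - 2 = 4
  expect_equal(split_join(t), 4L)
})

test_that("indices are label-permutation invariant and within range on random pairs", {
  set.seed(33)
  for (rep in 1:200) {
    N <- sample(5:40, 1)
    a <- random_labels(N, sample(2:6, 1))
    b <- random_labels(N, sample(2:6, 1))
    t <- contingency(chip_partition(a), chip_partition(b))
    r <- compare_all(chip_partition(a), chip_partition(b))
    expect_gte(r$nmi, 0); expect_lte(r$nmi, 1 + 1e-12)
    expect_gte(r$vi, 0)
    expect_lte(r$vi, 2 * log(max(max(a), max(b))) + 1e-12)
    expect_gte(r$sj, 0L); expect_lte(r$sj, 2L * N)
    expect_gte(r$ari, -1); expect_lte(r$ari, 1)
    expect_lte(r$jaccard, r$fm + 1e-12)   # J <= FM always
    pa <- sample.int(max(a)); pb <- sample.int(max(b))
    r2 <- compare_all(chip_partition(pa[a], max(a)),
                      chip_partition(pb[b], max(b)))
    expect_equal(unlist(r), unlist(r2), tolerance = 1e-12)
  }
})

test_that("VI is a metric on random partition triples", {
  set.seed(44)
  for (rep in 1:50) {
    N <- 30
    a <- random_labels(N, 4); b <- random_labels(N, 4); c_ <- random_labels(N, 4)
    vab <- vi(contingency(chip_partition(a), chip_partition(b)))
    vbc <- vi(contingency(chip_partition(b), chip_partition(c_)))
    vac <- vi(contingency(chip_partition(a), chip_partition(c_)))
    expect_lte(vac, vab + vbc + 1e-9)
  }
})

test_that("ARI is centered at zero under random label pairings", {
  set.seed(55)
  a <- rep(1:4, each = 15)          # fixed reference, 60 items
  n_draws <- 4000
  vals <- replicate(n_draws, {
    b <- sample(a)                  # random labels with the same sizes
    ari(contingency(chip_partition(a), chip_partition(b)))
  })
  se <- stats::sd(vals) / sqrt(n_draws)
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("ARI agrees with an independent library implementation", {
  set.seed(66)
  for (rep in 1:25) {
    a <- random_labels(50, 5); b <- random_labels(50, 7)
    expect_equal(ari(contingency(chip_partition(a), chip_partition(b))),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("degenerate tables follow the documented conventions", {
  # single cluster vs single cluster: identical, NMI 1, VI 0
  t <- contingency(chip_partition(rep(1L, 5), 1), chip_partition(rep(1L, 5), 1))
  expect_equal(nmi(t), 1)
  expect_equal(vi(t), 0)
  # all singletons vs all singletons: no co-clustered pairs anywhere
  t2 <- contingency(chip_partition(1:5, 5), chip_partition(1:5, 5))
  expect_equal(jaccard_pairs(t2), 0)
  expect_equal(fowlkes_mallows(t2), 0)
  expect_equal(ari(t2), 1)   # still identical clusterings
  expect_error(ari(contingency(chip_partition(1L, 1), chip_partition(1L, 1))),
               "at least 2")
})
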
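test_that("faith_pd matches hand-enumerated spanning subtrees on the balanced fixture", {
  tr <- balanced4()
  expect_equal(faith_pd(tr, c("A", "B")), 2)          # two pendant edges, MRCA stem excluded
  expect_equal(faith_pd(tr, "A"), 0)                  # singleton convention
  expect_equal(faith_pd(tr, c("A", "C")), 4)          # pendants + both internal edges
  expect_equal(faith_pd(tr, c("A", "B", "C", "D")), 6)
  expect_error(faith_pd(tr, c("A", "Z")), "not in tree")
})

test_that("faith_pd agrees with the closed-tour oracle and is monotone under leaf addition", {
  set.seed(101)
  for (rep in 1:25) {
    tr <- ape::rtree(sample(5:15, 1))
    tips <- sample(tr$tip.label, sample(2:ape::Ntip(tr), 1))
    expect_equal(faith_pd(tr, tips), tour_pd(tr, tips), tolerance = 1e-9)
    extra <- setdiff(tr$tip.label, tips)
    if (length(extra)) {
      expect_gte(faith_pd(tr, c(tips, sample(extra, 1))), faith_pd(tr, tips) - 1e-12)
    }
  }
})

test_that("extremal subsets are exact on the balanced fixture and at the boundary sizes", {
  tr <- balanced4()
  mn <- min_pd_subset(tr, 2)
  expect_equal(mn$pd, 2)                        # a cherry
  expect_true(setequal(mn$leaves, c("A", "B")) || setequal(mn$leaves, c("C", "D")))
  expect_equal(max_pd_subset(tr, 4)$pd, 6)      # only one subset at k = n
  expect_equal(min_pd_subset(tr, 4)$pd, 6)
  expect_equal(max_pd_subset(tr, 1)$pd, 0)
  expect_error(max_pd_subset(tr, 0), "between")
  expect_error(min_pd_subset(tr, 5), "between")
})

test_that("greedy max and DP min match exhaustive enumeration on random trees", {
  # a light sweep; the full 200-tree equivalence sweep lives with the
  # acceptance checks
  set.seed(202)
  for (rep in 1:25) {
    tr <- ape::rtree(sample(6:10, 1))
    n <- ape::Ntip(tr)
    for (k in 2:n) {
      rng <- brute_pd_range(tr, k)
      mx <- max_pd_subset(tr, k)
      mn <- min_pd_subset(tr, k)
      expect_equal(mx$pd, rng[["max"]], tolerance = 1e-9)
      expect_equal(mn$pd, rng[["min"]], tolerance = 1e-9)
      # returned sets attain their reported values
      expect_equal(faith_pd(tr, mx$leaves), mx$pd, tolerance = 1e-9)
      expect_equal(faith_pd(tr, mn$leaves), mn$pd, tolerance = 1e-9)
    }
  }
})

test_that("sampled PD range is bracketed by the exact extremes and is seed-stable", {
  set.seed(303)
  tr <- ape::rtree(12)
  for (k in c(1, 3, 6)) {
    s1 <- sample_pd_range(tr, k, n_samples = 50, seed = 9)
    s2 <- sample_pd_range(tr, k, n_samples = 50, seed = 9)
    expect_identical(s1, s2)
    expect_gte(s1[["min"]], min_pd_subset(tr, k)$pd - 1e-12)
    expect_lte(s1[["max"]], max_pd_subset(tr, k)$pd + 1e-12)
  }
  expect_equal(unname(sample_pd_range(tr, 1, 5, seed = 1)), c(0, 0))
})

test_that("scaled PD hits 0 and 1 at the extremal sets and is flagged when degenerate", {
  set.seed(404)
  tr <- ape::rtree(10)
  k <- 4
  mx <- max_pd_subset(tr, k)
  mn <- min_pd_subset(tr, k)
  expect_equal(scaled_pd(tr, mx$leaves)$scaled_pd, 1)
  expect_equal(scaled_pd(tr, mn$leaves)$scaled_pd, 0)
  expect_true(is.na(scaled_pd(tr, tr$tip.label)$scaled_pd))  # single possible subset
  mid <- scaled_pd(tr, sample(tr$tip.label, 5))
  expect_gte(mid$scaled_pd, 0)
  expect_lte(mid$scaled_pd, 1)
  expect_true(mid$pd_min <= mid$pd && mid$pd <= mid$pd_max)
})

test_that("pd_extremes matches per-size calls across all sizes of one tree", {
  set.seed(505)
  tr <- ape::rtree(12)
  ext <- pd_extremes(tr, 1:12)
  for (k in c(1, 2, 5, 9, 12)) {
    expect_equal(ext$pd_min[ext$k == k], min_pd_subset(tr, k)$pd, tolerance = 1e-9)
    expect_equal(ext$pd_max[ext$k == k], max_pd_subset(tr, k)$pd, tolerance = 1e-9)
  }
})
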
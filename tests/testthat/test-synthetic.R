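small_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_fungi = 30, n_plants = 8, n_localities = 5,
                   multi_species_localities = 3, host_count_range = c(2, 10),
                   locality_pool_size = 12, community_sizes = c(2, 3),
                   multi_species_counts = c(4, 3, 2),
                   specimens_per_species_range = c(1, 5), ...)
}

test_that("generated trees are ultrametric, correctly sized and seed-reproducible", {
  cfg <- synthetic_config(seed = 4)
  tr <- generate_tree(cfg)
  expect_equal(ape::Ntip(tr), 138)
  depths <- ape::node.depth.edgelength(tr)[seq_len(138)]
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_identical(ape::write.tree(tr), ape::write.tree(generate_tree(cfg)))
  tiny <- generate_tree(synthetic_config(seed = 1, n_fungi = 2, n_plants = 2,
                                         n_localities = 1, multi_species_localities = 1,
                                         host_count_range = c(1, 2), locality_pool_size = 2,
                                         community_sizes = 2, multi_species_counts = 2))
  expect_equal(ape::Ntip(tiny), 2)
})

test_that("config validation rejects infeasible settings", {
  expect_error(synthetic_config(seed = 1, pool_sharing = 1.2), "pool_sharing")
  expect_error(synthetic_config(seed = 1, host_count_range = c(0, 42)), "host_count_range")
  expect_error(synthetic_config(seed = 1, pool_sharing = 1, locality_pool_size = 10),
               "infeasible")
  expect_error(synthetic_config(seed = 1, multi_species_counts = rep(2, 3)),
               "one entry per")
  expect_error(
    synthetic_config(seed = 1, n_fungi = 30, n_plants = 8, n_localities = 5,
                     multi_species_localities = 3, host_count_range = c(2, 10),
                     locality_pool_size = 12, community_sizes = c(2, 6),
                     multi_species_counts = c(4, 3, 2)),
    "rich enough"
  )
})

test_that("generated datasets satisfy every structural invariant of the survey design", {
  cfg <- synthetic_config(seed = 21)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(cross_validate(ds$host_tree, ds$incidence, ds$metadata, ds$communities)), 0)
  d <- host_counts(ds$incidence)
  expect_true(all(d >= cfg$host_count_range[1] & d <= cfg$host_count_range[2]))
  expect_equal(length(d), 20)
  expect_equal(ncol(ds$incidence) - 1, 138)
  # 15 localities, 9 of them multi-species
  occ <- table(unique(ds$metadata[, c("plant_id", "locality")])$locality)
  expect_equal(length(occ), 15)
  expect_equal(sum(occ >= 2), 9)
  # observed communities have the configured size multiset and co-occur
  sizes <- sort(as.integer(table(ds$communities$community_id)))
  expect_equal(sizes, sort(cfg$community_sizes))
  for (cid in unique(ds$communities$community_id)) {
    members <- ds$communities$plant_id[ds$communities$community_id == cid]
    expect_true(classify_location(members, ds$metadata))
  }
  # full determinism under one seed
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$incidence, ds2$incidence)
  expect_identical(ds$metadata, ds2$metadata)
  expect_identical(ape::write.tree(ds$host_tree), ape::write.tree(ds2$host_tree))
})

test_that("locality pooling concentrates host sharing within localities", {
  # with full pooling, pairs that co-occur at a locality share more hosts
  # than pairs that never do; without pooling the two are alike
  gap <- function(ps, seed) {
    ds <- generate_dataset(small_cfg(seed = seed, pool_sharing = ps))
    O <- pairwise_matrix(ds$incidence, "overlap")
    same <- outer(rownames(O), colnames(O),
                  Vectorize(function(i, j) i != j && classify_location(c(i, j), ds$metadata)))
    mean(O[same & upper.tri(O)]) - mean(O[!same & upper.tri(O)])
  }
  gaps_hi <- vapply(1:6, function(s) gap(1, s), numeric(1))
  gaps_lo <- vapply(1:6, function(s) gap(0, s), numeric(1))
  expect_gt(mean(gaps_hi), 0.05)
  expect_gt(mean(gaps_hi), mean(gaps_lo) + 0.05)
})

test_that("fixtures round-trip and validate", {
  ds <- generate_dataset(small_cfg(seed = 3))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_fixture(ds, dir1)
  back <- read_fixture(dir1)
  expect_equal(nrow(cross_validate(back$host_tree, back$incidence, back$metadata,
                                   back$communities)), 0)
  ds_back <- structure(c(back, list(config = NULL)), class = "myco_dataset")
  names(ds_back)[1] <- "host_tree"
  write_fixture(ds_back, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir2, f)), readLines(file.path(dir1, f)), label = f)
  }
})
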
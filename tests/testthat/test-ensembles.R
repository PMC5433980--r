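test_that("group enumeration is exhaustive and deterministic", {
  g <- enumerate_groups(c("a", "b", "c", "d"), 2)
  expect_equal(nrow(g), 6)
  expect_equal(g$members[[1]], c("a", "b"))
  expect_equal(g$members[[6]], c("c", "d"))
  expect_equal(nrow(enumerate_groups(letters[1:6], 3)), choose(6, 3))
  expect_error(enumerate_groups(c("a", "b"), 3), "between")
  expect_error(enumerate_groups(c("a", "a"), 2), "distinct")
})

test_that("location classification uses existential common-locality semantics", {
  meta <- tibble::tibble(
    plant_id = c("p1", "p1", "p2", "p2", "p3", "p4"),
    family = "F",
    locality = c("Laussat", "Elie", "Laussat", "Singes", "Singes", "Elie"),
    n_specimens = 1L
  )
  expect_true(classify_location(c("p1", "p2"), meta))        # share Laussat
  expect_true(classify_location(c("p2", "p3"), meta))        # share Singes
  expect_false(classify_location(c("p1", "p3"), meta))       # no common locality
  expect_false(classify_location(c("p1", "p2", "p3"), meta)) # pairwise overlap, no common site
  expect_true(classify_location(c("p1", "p4"), meta))        # multi-locality species, Elie shared
  expect_error(classify_location(c("p1", "ghost"), meta), "missing")

  # monotone: removing a member never turns TRUE into FALSE
  set.seed(1)
  for (rep in 1:20) {
    g <- sample(c("p1", "p2", "p3", "p4"), sample(2:4, 1))
    if (classify_location(g, meta) && length(g) > 2) {
      expect_true(classify_location(g[-1], meta))
    }
  }
})

test_that("group covariates: specimen totals, pooled OTU count, Herfindahl index", {
  inc <- toy_incidence3()
  meta <- toy_metadata3()
  cov1 <- group_covariates(c("pA", "pB", "pC"), inc, meta)
  expect_equal(cov1$total_specimens, 2L + 2L + 1L)
  expect_equal(cov1$total_otus, 5L)
  expect_equal(cov1$herfindahl, (2/5)^2 + (2/5)^2 + (1/5)^2)
  # equal counts over s members -> 1/s; single member -> 1
  meta_eq <- tibble::tibble(plant_id = c("pA", "pB", "pC"), family = "F",
                            locality = "L", n_specimens = 3L)
  expect_equal(group_covariates(c("pA", "pB", "pC"), inc, meta_eq)$herfindahl, 1/3)
  expect_equal(group_covariates("pA", inc, meta_eq)$herfindahl, 1)
  # counts (2,1,1) -> 0.375
  meta_211 <- tibble::tibble(plant_id = c("pA", "pB", "pC"), family = "F",
                             locality = "L", n_specimens = c(2L, 1L, 1L))
  expect_equal(group_covariates(c("pA", "pB", "pC"), inc, meta_211)$herfindahl, 0.375)
})

test_that("ensemble scaling spans [0,1], flags degenerate ranges, and matches vectorised metrics", {
  fx <- read_fixture(fixture_dir())
  ens <- build_ensemble(fx$host_tree, fx$incidence, fx$metadata, 3, fx$communities)
  gen <- ens[ens$provenance == "generated", ]
  expect_equal(nrow(gen), choose(6, 3))
  expect_equal(min(gen$scaled_pd), 0)
  expect_equal(max(gen$scaled_pd), 1)
  expect_equal(min(gen$scaled_overlap), 0)
  expect_equal(max(gen$scaled_overlap), 1)
  expect_true(all(ens$scaled_pd >= 0 & ens$scaled_pd <= 1))

  # vectorised PD and overlap agree with the per-group functions
  for (i in sample(nrow(gen), 5)) {
    expect_equal(gen$combined_pd[i], combined_pd(fx$host_tree, fx$incidence, gen$members[[i]]),
                 tolerance = 1e-9)
    expect_equal(gen$overlap[i], group_overlap(fx$incidence, gen$members[[i]]),
                 tolerance = 1e-12)
  }

  # observed communities are scaled against the generated range: a community
  # equal to some generated group inherits its scaled values
  obs <- ens[ens$provenance == "observed", ]
  if (nrow(obs) > 0) {
    key <- vapply(gen$members, paste, character(1), collapse = "|")
    for (i in seq_len(nrow(obs))) {
      hit <- match(paste(obs$members[[i]], collapse = "|"), key)
      expect_false(is.na(hit))
      expect_equal(obs$scaled_pd[i], gen$scaled_pd[hit])
    }
  }

  # degenerate range flags NA
  ens0 <- ens[, ]
  ens0$overlap <- 0.3
  expect_true(all(is.na(scale_within_ensemble(ens0)$scaled_overlap)))
})

test_that("sum-based and mean-based group overlap scale identically within a size", {
  fx <- read_fixture(fixture_dir())
  ens <- build_ensemble(fx$host_tree, fx$incidence, fx$metadata, 3)
  ens_sum <- ens
  ens_sum$overlap <- ens$overlap * choose(3, 2)  # the summed form of the same statistic
  expect_equal(scale_within_ensemble(ens_sum)$scaled_overlap,
               scale_within_ensemble(ens)$scaled_overlap, tolerance = 1e-12)
})
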
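random_dist <- function(n) as.matrix(stats::dist(stats::runif(n)))

test_that("Mantel statistic is exact on self- and scaled-comparisons and seed-stable", {
  set.seed(7)
  A <- random_dist(8)
  expect_equal(mantel_test(A, A, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(A, 2 * A, n_perm = 99, seed = 1)$r, 1)  # Pearson scale invariance
  set.seed(11); B <- random_dist(8)
  m1 <- mantel_test(A, B, n_perm = 499, seed = 42)
  m2 <- mantel_test(A, B, n_perm = 499, seed = 42)
  expect_identical(m1, m2)
  expect_gte(m1$p, 1 / (499 + 1))
  expect_true(mantel_test(A, matrix(1, 8, 8) - diag(8) * 0, n_perm = 9)$degenerate)
  expect_error(mantel_test(A[1:2, 1:2], A[1:2, 1:2]), "at least 3")
})

test_that("Mantel agrees with vegan on r and approximately on p", {
  set.seed(99)
  A <- random_dist(12); B <- as.matrix(stats::dist(stats::runif(12) + 0.5 * A[, 1]))
  mine <- mantel_test(A, B, n_perm = 999, seed = 3)
  ref <- vegan::mantel(stats::as.dist(A), stats::as.dist(B), permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p - ref$signif), 0.05)
})

test_that("patristic distances come from path-length sums", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(phylo_distance_matrix(cherry)["A", "B"], 2)
  tr <- balanced4()
  D <- phylo_distance_matrix(tr, c("A", "C", "B"))
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_equal(D["A", "C"], 4)
  expect_equal(colnames(D), c("A", "C", "B"))  # caller ordering respected
  expect_error(phylo_distance_matrix(tr, "Z"), "not in tree")
})

test_that("Pearson correlation matches the closed-form oracle", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.3)
  y <- c(2.0, 2.9, 4.2, 4.1, 6.8, 6.9)
  res <- pearson_cor(x, y)
  # direct product-moment formula, written out independently
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_direct <- r_direct * sqrt((length(x) - 2) / (1 - r_direct^2))
  p_direct <- 2 * stats::pt(-abs(t_direct), length(x) - 2)
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(res$p, p_direct, tolerance = 1e-12)
  expect_equal(res$df, length(x) - 2L)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_true(pearson_cor(x, rep(1, 6))$degenerate)
})

test_that("partial correlation matches the single-covariate recursion formula", {
  set.seed(5)
  n <- 40
  z <- rnorm(n)
  x <- 0.6 * z + rnorm(n)
  y <- -0.4 * z + rnorm(n)
  res <- partial_pearson(x, y, matrix(z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  r_oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$df, n - 3L)

  # no covariates reduces to plain Pearson
  p0 <- partial_pearson(x, y, matrix(numeric(0), nrow = n, ncol = 0))
  p1 <- pearson_cor(x, y)
  expect_equal(p0$r, p1$r)
  expect_equal(p0$p, p1$p)

  # y an exact linear function of the covariates -> residual correlation 0
  y_lin <- 2 + 3 * z
  expect_true(partial_pearson(x, y_lin, matrix(z))$degenerate)
  expect_error(partial_pearson(x, y, cbind(z, 2 * z)), "rank-deficient")
})

test_that("Welch comparison matches its defining formulas and brackets true shifts", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.2)
  res <- welch_t_test(a, b)
  # Welch-Satterthwaite written out directly
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  t_direct <- (mean(a) - mean(b)) / se
  df_direct <- se^4 / ((var(a) / length(a))^2 / (length(a) - 1) +
                       (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(res$t, t_direct, tolerance = 1e-12)
  expect_equal(res$df, df_direct, tolerance = 1e-9)
  expect_equal(res$p, 2 * stats::pt(-abs(t_direct), df_direct), tolerance = 1e-12)
  expect_true(res$ci_low <= res$mean_a - res$mean_b && res$mean_a - res$mean_b <= res$ci_high)

  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_true(same$ci_low < 0 && same$ci_high > 0)

  set.seed(8)
  big_a <- rnorm(4000, mean = 1.5); big_b <- rnorm(4000, mean = 1.0)
  shift <- welch_t_test(big_a, big_b)
  expect_lt(abs((shift$mean_a - shift$mean_b) - 0.5), 0.1)
  expect_true(shift$ci_low < 0.5 && shift$ci_high > 0.4)

  expect_true(welch_t_test(c(1, 1, 1), c(2, 2))$degenerate)
})

test_that("tidiers return one-row tibbles with the documented fields", {
  set.seed(2)
  A <- random_dist(6); B <- random_dist(6)
  td <- tidy(mantel_test(A, B, n_perm = 99, seed = 1))
  expect_named(td, c("r", "p.value", "n_perm", "n", "degenerate"))
  expect_equal(nrow(td), 1)
  td2 <- tidy(pearson_cor(rnorm(10), rnorm(10)))
  expect_true(all(c("r", "p.value", "df") %in% names(td2)))
  td3 <- glance(welch_t_test(rnorm(5), rnorm(5)))
  expect_true(all(c("estimate", "ci_low", "ci_high") %in% names(td3)))
})
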
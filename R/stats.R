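# Permutation Mantel tests, Pearson / partial Pearson correlations, Welch
# two-sample comparisons, and broom-style tidiers for their results.

align_square <- function(a, b) {
  if (!isTRUE(all.equal(dim(a), dim(b)))) abort("matrices must have equal dimensions")
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb)) {
    if (!setequal(la, lb)) abort("matrix labels do not match")
    b <- b[la, la, drop = FALSE]
  }
  list(a = a, b = b)
}

#' Permutation Mantel test
#'
#' Correlates the upper triangles of two symmetric pairwise matrices and
#' assesses significance by jointly permuting the rows and columns of the
#' second matrix. The alternative is one-sided ("greater"), with
#' p = (count(r_perm >= r_obs) + 1) / (n_perm + 1), the convention of
#' vegan's `mantel`. A matrix with constant upper triangle is flagged
#' degenerate (r and p are `NA`).
#'
#' @param dist_a,dist_b Symmetric numeric matrices with matching dimnames
#'   (the second is realigned to the first when orders differ).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed; a fixed seed reproduces the result
#'   exactly.
#' @return An object of class `myco_mantel` with fields `r`, `p`,
#'   `n_perm`, `n`, `seed`, `degenerate`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 10000, seed = NULL) {
  al <- align_square(as.matrix(dist_a), as.matrix(dist_b))
  a <- al$a; b <- al$b
  n <- nrow(a)
  if (n < 3) abort("Mantel test needs matrices of dimension at least 3")
  av <- upper_tri_vec(a)
  bv <- upper_tri_vec(b)
  out <- structure(list(r = NA_real_, p = NA_real_, n_perm = as.integer(n_perm),
                        n = n, seed = seed, degenerate = FALSE),
                   class = "myco_mantel")
  if (sd(av) == 0 || sd(bv) == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  r_obs <- cor(av, bv)
  ut <- upper.tri(b)
  perm_r <- with_opt_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(av, b[p, p][ut])
    }, numeric(1))
  })
  out$r <- r_obs
  out$p <- (sum(perm_r >= r_obs) + 1) / (n_perm + 1)
  out
}

#' Patristic distance matrix between taxa
#'
#' Pairwise sums of branch lengths along the paths of a phylogeny.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param taxa Optional character vector selecting and ordering tips.
#' @return A symmetric numeric matrix.
#' @export
phylo_distance_matrix <- function(tree, taxa = NULL) {
  check_tree(tree)
  D <- cophenetic(tree)
  if (!is.null(taxa)) {
    taxa <- as.character(taxa)
    match_tips(tree, taxa)
    D <- D[taxa, taxa, drop = FALSE]
  }
  D
}

new_cor_result <- function(r, p, df, n, n_covariates, degenerate = FALSE) {
  structure(list(r = r, p = p, df = df, n = n, n_covariates = n_covariates,
                 degenerate = degenerate), class = "myco_cor")
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return An object of class `myco_cor` with `r`, `p`, `df` (= n - 2).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {  # all-NA metrics (e.g. degenerate scaling) fall through as degenerate
    return(new_cor_result(NA_real_, NA_real_, NA_integer_, n, 0L, degenerate = TRUE))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(new_cor_result(NA_real_, NA_real_, n - 2L, n, 0L, degenerate = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  new_cor_result(unname(ct$estimate), ct$p.value, as.integer(ct$parameter), n, 0L)
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after least-squares projection
#' on the covariates (plus intercept); the two-sided p-value uses a
#' t-distribution with df = n - 2 - q for q covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates A numeric matrix or data frame of covariates (may have
#'   zero columns, in which case this reduces to [pearson_cor()]).
#' @return An object of class `myco_cor`.
#' @export
partial_pearson <- function(x, y, covariates) {
  Z <- as.matrix(covariates)
  if (ncol(Z) == 0) return(pearson_cor(x, y))
  if (nrow(Z) != length(x) || length(x) != length(y)) {
    abort("`x`, `y` and `covariates` must have matching lengths")
  }
  if (length(x) <= ncol(Z) + 2) abort("need n > number of covariates + 2")
  ok <- stats::complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  q <- ncol(Z)
  if (n <= q + 2) {
    return(new_cor_result(NA_real_, NA_real_, NA_integer_, n, as.integer(q), degenerate = TRUE))
  }
  X <- cbind(1, Z)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) abort("rank-deficient covariates")
  rx <- qr.resid(qr_x, x)
  ry <- qr.resid(qr_x, y)
  # residuals that vanish to rounding error mean x or y is (numerically) a
  # linear function of the covariates: flag, don't divide by ~0
  if (sd(rx) <= 1e-12 * max(sd(x), 1) || sd(ry) <= 1e-12 * max(sd(y), 1)) {
    return(new_cor_result(NA_real_, NA_real_, as.integer(n - 2 - q), n, as.integer(q),
                          degenerate = TRUE))
  }
  r <- cor(rx, ry)
  df <- n - 2 - q
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  new_cor_result(r, p, as.integer(df), n, as.integer(q))
}

#' Welch two-sample comparison
#'
#' Unequal-variance t-test with a 95% confidence interval for
#' mean(a) - mean(b), using the Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return An object of class `myco_ttest` with `mean_a`, `mean_b`, `t`,
#'   `df`, `p`, `ci_low`, `ci_high`; degenerate when both samples have zero
#'   variance.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each sample needs at least 2 observations")
  out <- structure(list(mean_a = mean(a), mean_b = mean(b), t = NA_real_,
                        df = NA_real_, p = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_a = length(a), n_b = length(b),
                        degenerate = FALSE), class = "myco_ttest")
  if (sd(a) == 0 && sd(b) == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  tt <- t.test(a, b, var.equal = FALSE, conf.level = 0.95)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out$ci_low <- tt$conf.int[1]
  out$ci_high <- tt$conf.int[2]
  out
}

#' @export
print.myco_mantel <- function(x, ...) {
  if (x$degenerate) {
    cat("Mantel test: degenerate (constant matrix)\n")
  } else {
    cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d permutations, n = %d)\n",
                x$r, x$p, x$n_perm, x$n))
  }
  invisible(x)
}

#' @export
print.myco_cor <- function(x, ...) {
  lab <- if (x$n_covariates > 0) sprintf("partial Pearson (q = %d)", x$n_covariates) else "Pearson"
  if (x$degenerate) {
    cat(lab, "correlation: degenerate (constant input)\n")
  } else {
    cat(sprintf("%s correlation: r = %.3f, df = %d, p = %.4g\n", lab, x$r, x$df, x$p))
  }
  invisible(x)
}

#' @export
print.myco_ttest <- function(x, ...) {
  cat(sprintf("Welch t-test: mean_a = %.3f, mean_b = %.3f, t = %.3f, p = %.4g, 95%% CI [%.3f, %.3f]\n",
              x$mean_a, x$mean_b, x$t, x$p, x$ci_low, x$ci_high))
  invisible(x)
}

#' Tidy a Mantel result
#' @param x A `myco_mantel` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::tidy
tidy.myco_mantel <- function(x, ...) {
  tibble::tibble(r = x$r, p.value = x$p, n_perm = x$n_perm, n = x$n,
                 degenerate = x$degenerate)
}

#' @rdname tidy.myco_mantel
#' @exportS3Method generics::glance
glance.myco_mantel <- function(x, ...) tidy.myco_mantel(x)

#' Tidy a correlation result
#' @param x A `myco_cor` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::tidy
tidy.myco_cor <- function(x, ...) {
  tibble::tibble(r = x$r, p.value = x$p, df = x$df, n = x$n,
                 n_covariates = x$n_covariates, degenerate = x$degenerate)
}

#' @rdname tidy.myco_cor
#' @exportS3Method generics::glance
glance.myco_cor <- function(x, ...) tidy.myco_cor(x)

#' Tidy a Welch t-test result
#' @param x A `myco_ttest` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::tidy
tidy.myco_ttest <- function(x, ...) {
  tibble::tibble(mean_a = x$mean_a, mean_b = x$mean_b, estimate = x$mean_a - x$mean_b,
                 t = x$t, df = x$df, p.value = x$p,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_a = x$n_a, n_b = x$n_b, degenerate = x$degenerate)
}

#' @rdname tidy.myco_ttest
#' @exportS3Method generics::glance
glance.myco_ttest <- function(x, ...) tidy.myco_ttest(x)
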
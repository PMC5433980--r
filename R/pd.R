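# Faith phylogenetic diversity and exact extremal-PD subset algorithms.
#
# PD convention used throughout: the total branch length of the minimal
# subtree spanning a leaf set, EXCLUDING the stem edge above the set's most
# recent common ancestor (equivalently, the unrooted spanning length).
# A singleton set has PD = 0. Under this convention the PD of the full leaf
# set equals the sum of all edge lengths minus any root stem.

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths; PD is undefined")
  if (anyNA(tree$edge.length)) abort("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  invisible(tree)
}

match_tips <- function(tree, leaves) {
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx)) {
    abort(paste0("leaf label(s) not in tree: ", paste(leaves[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Faith phylogenetic diversity of a leaf set
#'
#' Sums the branch lengths of the minimal subtree spanning `leaves`,
#' excluding the stem edge above their most recent common ancestor. A
#' singleton leaf set has PD 0 by convention.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param leaves Character vector of tip labels (duplicates ignored).
#' @return A single non-negative number in the tree's branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' faith_pd(tr, c("A", "B"))   # 2
#' faith_pd(tr, c("A", "C"))   # 4
#' @export
faith_pd <- function(tree, leaves) {
  check_tree(tree)
  leaves <- unique(as.character(leaves))
  if (length(leaves) == 0) abort("`leaves` must be non-empty")
  tip_idx <- match_tips(tree, leaves)
  m <- length(tip_idx)
  if (m == 1) return(0)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  cnt <- numeric(ntip + tr$Nnode)
  cnt[tip_idx] <- 1
  e <- tr$edge
  for (i in seq_len(nrow(e))) cnt[e[i, 1]] <- cnt[e[i, 1]] + cnt[e[i, 2]]
  below <- cnt[e[, 2]]
  sum(tr$edge.length[below > 0 & below < m])
}

# Full node-to-node distance matrix plus bookkeeping reused by the greedy
# max-PD search.
greedy_pd_sequence <- function(tree) {
  check_tree(tree)
  ntip <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  tipD <- D[seq_len(ntip), seq_len(ntip), drop = FALSE]
  tol <- 1e-12 * max(1, max(D))

  # Seed with the tree diameter pair (required for greedy optimality);
  # break ties toward the lexicographically smallest label pair.
  best <- max(tipD)
  cand <- which(tipD >= best - tol & upper.tri(tipD), arr.ind = TRUE)
  lab <- tree$tip.label
  pair_key <- vapply(seq_len(nrow(cand)), function(r) {
    p <- sort(c(lab[cand[r, 1]], lab[cand[r, 2]]))
    paste(p, collapse = "\r")
  }, character(1))
  pick <- cand[order(pair_key)[1], ]
  i <- pick[[1]]; j <- pick[[2]]

  path_nodes <- function(a, b) which(D[a, ] + D[, b] <= D[a, b] + tol)

  sub_nodes <- path_nodes(i, j)
  dmin <- apply(D[, sub_nodes, drop = FALSE], 1, min)
  chosen <- c(i, j)
  pd <- c(0, unname(tipD[i, j]))

  remaining <- setdiff(seq_len(ntip), chosen)
  while (length(remaining) > 0) {
    gains <- dmin[remaining]
    g <- max(gains)
    cand_tips <- remaining[gains >= g - tol]
    v <- cand_tips[order(lab[cand_tips])[1]]
    g <- unname(dmin[v])  # attachment length of v, before the subtree absorbs its path
    entry <- sub_nodes[which.min(D[v, sub_nodes])]
    new_nodes <- setdiff(path_nodes(v, entry), sub_nodes)
    if (length(new_nodes) > 0) {
      sub_nodes <- c(sub_nodes, new_nodes)
      dmin <- pmin(dmin, apply(D[, new_nodes, drop = FALSE], 1, min))
    }
    chosen <- c(chosen, v)
    pd <- c(pd, pd[length(pd)] + g)
    dmin[v] <- 0
    remaining <- setdiff(remaining, v)
  }
  list(order = lab[chosen], pd = pd)
}

#' Maximum-PD subset of a given size
#'
#' Finds a k-leaf set attaining the exact maximum Faith PD over all
#' k-subsets of the tree's leaves, by greedy leaf addition starting from the
#' tree-diameter pair. The greedy algorithm is provably optimal for maximum
#' PD and its solutions are nested across k. Ties are broken toward the
#' lexicographically smallest leaf label.
#'
#' @inheritParams faith_pd
#' @param k Subset size, between 1 and the number of leaves.
#' @return A list with `leaves` (character vector of length `k`) and `pd`.
#' @export
max_pd_subset <- function(tree, k) {
  check_tree(tree)
  ntip <- length(tree$tip.label)
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > ntip) abort("`k` must be between 1 and the number of leaves")
  if (k == 1) return(list(leaves = sort(tree$tip.label)[1], pd = 0))
  g <- greedy_pd_sequence(tree)
  list(leaves = g$order[seq_len(k)], pd = g$pd[k])
}

# Dynamic program over the rooted tree: cost[v][j] = minimal total edge
# length of a connected subgraph containing node v and exactly j leaves of
# v's clade (stem above v not counted). Children are folded in by min-plus
# convolution. The minimum over ALL nodes of cost[.][k] is the exact min-PD:
# any connected subgraph contains the spanning subtree of its leaves, and at
# the true MRCA the bound is attained.
min_pd_tables <- function(tree, kmax, keep_acc = FALSE) {
  check_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kmax <- as.integer(kmax)
  tr <- ape::reorder.phylo(tree, "postorder")
  elen <- numeric(nnode)               # length of the edge above each node
  elen[tr$edge[, 2]] <- tr$edge.length
  kids <- split(tr$edge[, 2], factor(tr$edge[, 1], levels = seq_len(nnode)))

  cost <- matrix(Inf, nnode, kmax + 1)  # column j+1 holds j leaves
  cost[, 1] <- 0
  cost[seq_len(ntip), 2] <- 0
  accs <- if (keep_acc) vector("list", nnode) else NULL

  minplus <- function(a, b) {
    o <- outer(a, b, "+")
    vapply(seq_along(a), function(t) {
      idx <- seq_len(t)
      min(o[cbind(idx, rev(idx))])
    }, numeric(1))
  }

  internal <- unique(tr$edge[, 1])  # postorder: children before parents
  for (v in internal) {
    ch <- kids[[v]]
    acc <- c(0, rep(Inf, kmax))
    if (keep_acc) pre <- vector("list", length(ch))
    for (ci in seq_along(ch)) {
      c_node <- ch[ci]
      if (keep_acc) pre[[ci]] <- acc
      h <- c(0, cost[c_node, -1] + elen[c_node])
      acc <- minplus(acc, h)
    }
    cost[v, ] <- acc
    if (keep_acc) accs[[v]] <- list(children = ch, pre = pre)
  }
  list(cost = cost, elen = elen, accs = accs, ntip = ntip)
}

# Exact min-PD value for every j in 1..kmax (vector of length kmax).
min_pd_values <- function(tree, kmax) {
  tab <- min_pd_tables(tree, kmax)
  vals <- apply(tab$cost[, -1, drop = FALSE], 2, min)
  vals[1] <- 0
  vals
}

#' Minimum-PD subset of a given size
#'
#' Finds a k-leaf set attaining the exact minimum Faith PD over all
#' k-subsets, by dynamic programming over the tree: each node carries the
#' minimal spanning length for choosing j leaves within its clade, children
#' are combined by min-plus convolution, and the answer is minimised over
#' candidate ancestor nodes. Runs in O(n k^2).
#'
#' @inheritParams max_pd_subset
#' @return A list with `leaves` and `pd`.
#' @export
min_pd_subset <- function(tree, k) {
  check_tree(tree)
  ntip <- length(tree$tip.label)
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > ntip) abort("`k` must be between 1 and the number of leaves")
  if (k == 1) return(list(leaves = sort(tree$tip.label)[1], pd = 0))
  tab <- min_pd_tables(tree, k, keep_acc = TRUE)
  cost <- tab$cost
  tol <- 1e-9 * max(1, max(tree$edge.length))
  best <- min(cost[, k + 1])
  v_star <- which(cost[, k + 1] <= best + tol)[1]

  leaves <- integer(0)
  recover <- function(v, j) {
    if (v <= tab$ntip) {
      stopifnot(j == 1)
      leaves <<- c(leaves, v)
      return(invisible())
    }
    info <- tab$accs[[v]]
    target <- cost[v, j + 1]
    jj <- j
    for (ci in rev(seq_along(info$children))) {
      c_node <- info$children[ci]
      pre <- info$pre[[ci]]
      h <- c(0, cost[c_node, -1] + tab$elen[c_node])
      # smallest b consistent with the optimal split
      b_opt <- NA_integer_
      for (b in 0:jj) {
        if (pre[jj - b + 1] + h[b + 1] <= target + tol) { b_opt <- b; break }
      }
      stopifnot(!is.na(b_opt))
      if (b_opt > 0) recover(c_node, b_opt)
      jj <- jj - b_opt
      target <- pre[jj + 1]
    }
    stopifnot(jj == 0)
  }
  recover(v_star, k)
  list(leaves = sort(tree$tip.label[leaves]), pd = best)
}

#' Monte-Carlo PD range over random equal-size subsets
#'
#' Draws `n_samples` uniform k-subsets of the tree's leaves and returns the
#' minimum and maximum Faith PD observed. A sampling-based cross-check for
#' the exact extremal algorithms.
#'
#' @inheritParams max_pd_subset
#' @param n_samples Number of random subsets to draw.
#' @param seed Optional integer seed; the same seed reproduces the result.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
sample_pd_range <- function(tree, k, n_samples, seed = NULL) {
  check_tree(tree)
  ntip <- length(tree$tip.label)
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > ntip) abort("`k` must be between 1 and the number of leaves")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1) abort("`n_samples` must be >= 1")
  pds <- with_opt_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      faith_pd(tree, sample(tree$tip.label, k))
    }, numeric(1))
  })
  c(min = min(pds), max = max(pds))
}

#' Exact PD extremes for several subset sizes at once
#'
#' One greedy pass and one dynamic-programming pass give the exact maximum
#' and minimum PD for every requested size, which is how per-plant scaled PD
#' is normalised efficiently.
#'
#' @inheritParams faith_pd
#' @param ks Integer vector of subset sizes.
#' @return A tibble with columns `k`, `pd_min`, `pd_max`.
#' @export
pd_extremes <- function(tree, ks) {
  check_tree(tree)
  ks <- sort(unique(as.integer(ks)))
  ntip <- length(tree$tip.label)
  if (any(ks < 1 | ks > ntip)) abort("sizes in `ks` must be between 1 and the number of leaves")
  g <- greedy_pd_sequence(tree)
  mins <- min_pd_values(tree, max(ks))
  tibble::tibble(k = ks, pd_min = mins[ks], pd_max = g$pd[ks])
}

#' Scaled phylogenetic diversity of a host set
#'
#' Computes PD' = (PD - PDmin) / (PDmax - PDmin), where PDmin and PDmax are
#' the exact extremes of Faith PD over all subsets of the fungal pool with
#' the same number of hosts. PD' locates an observed host set within the
#' full range attainable at its size; it is `NA` (degenerate) when the
#' range collapses, e.g. when the host set is the whole pool.
#'
#' @inheritParams faith_pd
#' @return A one-row tibble: `k`, `pd`, `pd_min`, `pd_max`, `scaled_pd`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' scaled_pd(tr, c("A", "C"))  # the max-PD pair: scaled_pd == 1
#' @export
scaled_pd <- function(tree, leaves) {
  check_tree(tree)
  leaves <- unique(as.character(leaves))
  k <- length(leaves)
  pd <- faith_pd(tree, leaves)
  ext <- pd_extremes(tree, k)
  rng <- ext$pd_max - ext$pd_min
  sc <- if (rng > 1e-12 * max(1, ext$pd_max)) (pd - ext$pd_min) / rng else NA_real_
  tibble::tibble(k = k, pd = pd, pd_min = ext$pd_min, pd_max = ext$pd_max, scaled_pd = sc)
}
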
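# Pairwise and group-level host-sharing statistics.
#
# Notation: d_i is the number of fungal hosts of plant i (row sum of the
# binary incidence matrix) and C_ij the number of hosts shared by plants
# i and j.

#' Host counts per plant
#'
#' @param incidence Plant x fungus incidence: a tibble whose first column is
#'   the plant id followed by 0/1 fungus columns, or a named 0/1 matrix.
#' @return A named integer vector of host counts d_i.
#' @export
host_counts <- function(incidence) {
  m <- incidence_matrix(incidence)
  setNames(as.integer(rowSums(m)), rownames(m))
}

#' Number of fungal hosts shared by two plants
#'
#' @inheritParams host_counts
#' @param i,j Plant ids (distinct).
#' @return Integer C_ij, between 0 and min(d_i, d_j).
#' @export
shared_hosts <- function(incidence, i, j) {
  m <- incidence_matrix(incidence)
  idx <- match_plants(m, c(i, j))
  if (i == j) abort("`i` and `j` must be distinct plants")
  sum(m[idx[1], ] & m[idx[2], ])
}

#' Absolute difference in host counts
#'
#' The dissimilarity |d_i - d_j| used to test for phylogenetic signal on
#' host-set size.
#'
#' @inheritParams shared_hosts
#' @export
count_dissimilarity <- function(incidence, i, j) {
  d <- host_counts(incidence)
  idx <- match_plants(incidence_matrix(incidence), c(i, j))
  abs(d[idx[1]] - d[idx[2]])[[1]]
}

#' Bray-Curtis host dissimilarity (presence form)
#'
#' 1 - 2 C_ij / (d_i + d_j): shared hosts relative to the combined host
#' counts.
#'
#' @inheritParams shared_hosts
#' @return A number in [0, 1]; 0 iff the host sets are identical.
#' @export
bray_curtis <- function(incidence, i, j) {
  m <- incidence_matrix(incidence)
  idx <- match_plants(m, c(i, j))
  if (i == j) abort("`i` and `j` must be distinct plants")
  di <- sum(m[idx[1], ]); dj <- sum(m[idx[2], ])
  cij <- sum(m[idx[1], ] & m[idx[2], ])
  1 - 2 * cij / (di + dj)
}

#' Min-overlap host similarity
#'
#' C_ij / min(d_i, d_j): shared hosts relative to the maximum number that
#' could be shared by the pair.
#'
#' @inheritParams shared_hosts
#' @return A number in [0, 1]; 1 iff one host set is nested in the other.
#' @export
min_overlap <- function(incidence, i, j) {
  m <- incidence_matrix(incidence)
  idx <- match_plants(m, c(i, j))
  if (i == j) abort("`i` and `j` must be distinct plants")
  di <- sum(m[idx[1], ]); dj <- sum(m[idx[2], ])
  cij <- sum(m[idx[1], ] & m[idx[2], ])
  cij / min(di, dj)
}

#' Full pairwise matrix of a host-sharing measure
#'
#' @inheritParams host_counts
#' @param measure One of `"count"` (|d_i - d_j| dissimilarity),
#'   `"bray_curtis"` (dissimilarity) or `"overlap"` (min-overlap
#'   SIMILARITY; take `1 - m` for a dissimilarity).
#' @return A symmetric numeric matrix with plant ids as dimnames and a
#'   `measure` attribute.
#' @export
pairwise_matrix <- function(incidence, measure = c("count", "bray_curtis", "overlap")) {
  measure <- match.arg(measure)
  m <- incidence_matrix(incidence)
  if (nrow(m) < 2) abort("need at least two plants")
  d <- rowSums(m)
  storage.mode(m) <- "double"
  C <- m %*% t(m)
  out <- switch(measure,
    count = abs(outer(d, d, "-")),
    bray_curtis = 1 - 2 * C / outer(d, d, "+"),
    overlap = C / outer(d, d, pmin)
  )
  diag(out) <- if (measure == "overlap") 1 else 0
  dimnames(out) <- list(rownames(m), rownames(m))
  attr(out, "measure") <- measure
  out
}

#' Group host overlap
#'
#' Mean min-overlap over all unordered pairs in a group of plants: the
#' average fraction of shared fungal hosts relative to the maximum each
#' pair could share. Within a fixed group size this differs from the summed
#' form only by the constant pair count, so min-max scaling within
#' same-size ensembles is identical under either.
#'
#' @inheritParams host_counts
#' @param group Character vector of at least two plant ids.
#' @return A number in [0, 1].
#' @export
group_overlap <- function(incidence, group) {
  group <- unique(as.character(group))
  if (length(group) < 2) abort("`group` must contain at least two plants")
  O <- pairwise_matrix(incidence, "overlap")
  idx <- match_plants(incidence_matrix(incidence), group)
  sub <- O[idx, idx, drop = FALSE]
  mean(upper_tri_vec(sub))
}

#' Combined phylogenetic diversity of a group's pooled host set
#'
#' Faith PD of the union of the member plants' fungal host sets.
#'
#' @param tree Fungal host phylogeny (`phylo`, branch lengths required).
#' @inheritParams host_counts
#' @param group Character vector of one or more plant ids.
#' @export
combined_pd <- function(tree, incidence, group) {
  group <- unique(as.character(group))
  if (length(group) < 1) abort("`group` must be non-empty")
  m <- incidence_matrix(incidence)
  idx <- match_plants(m, group)
  hosts <- colnames(m)[colSums(m[idx, , drop = FALSE]) > 0]
  faith_pd(tree, hosts)
}
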
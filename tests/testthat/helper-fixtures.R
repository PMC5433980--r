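# Shared fixtures and independent oracles.

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# incidence with pairwise min-overlaps (A,B)=1, (A,C)=0, (B,C)=0.5
toy_incidence3 <- function() {
  tibble::tibble(
    plant_id = c("pA", "pB", "pC"),
    f1 = c(1, 1, 0), f2 = c(1, 1, 0), f3 = c(0, 1, 1), f4 = c(0, 1, 0), f5 = c(0, 0, 1)
  )
}

toy_metadata3 <- function() {
  tibble::tibble(
    plant_id = c("pA", "pB", "pB", "pC"),
    family = "Burmanniaceae",
    locality = c("L1", "L1", "L2", "L2"),
    n_specimens = c(2L, 1L, 1L, 1L)
  )
}

# Independent Faith-PD oracle: closed-tour identity. With the leaves of a
# subset visited in the tree's planar (cladewise) circular order, the tour
# walks every edge of the spanning subtree exactly twice, so PD is half the
# sum of consecutive patristic distances. Shares no code with faith_pd().
tour_pd <- function(tree, tips) {
  trc <- ape::reorder.phylo(tree, "cladewise")
  ord <- trc$tip.label[trc$edge[, 2][trc$edge[, 2] <= ape::Ntip(trc)]]
  s <- ord[ord %in% tips]
  m <- length(s)
  if (m < 2) return(0)
  D <- stats::cophenetic(trc)
  sum(D[cbind(s, s[c(2:m, 1)])]) / 2
}

# Exhaustive PD range over all k-subsets, via the tour oracle.
brute_pd_range <- function(tree, k) {
  subs <- utils::combn(tree$tip.label, k)
  pds <- apply(subs, 2, function(s) tour_pd(tree, s))
  c(min = min(pds), max = max(pds))
}

fixture_dir <- function() {
  system.file("extdata", "synthetic_survey", package = "mycoverlap")
}
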
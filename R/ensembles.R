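# Exhaustive same-size group ensembles, min-max scaling and location
# classification.
#
# A "group" is a set of plant species; the generated ensemble of size n
# contains every one of the choose(S, n) subsets of the species pool, and
# scaled metrics locate each group within the full range its size allows.

#' Enumerate all plant groups of a given size
#'
#' Produces every `choose(length(plant_ids), n)` subset, in deterministic
#' lexicographic order with respect to the input ordering.
#'
#' @param plant_ids Character vector of distinct plant ids.
#' @param n Group size, between 2 and `length(plant_ids)`.
#' @return A tibble with `group_id`, `n` and a `members` list-column.
#' @export
enumerate_groups <- function(plant_ids, n) {
  plant_ids <- as.character(plant_ids)
  if (anyDuplicated(plant_ids)) abort("`plant_ids` must be distinct")
  n <- as.integer(n)
  if (is.na(n) || n < 2 || n > length(plant_ids)) {
    abort("`n` must be between 2 and the number of plants")
  }
  combos <- combn(plant_ids, n)
  tibble::tibble(
    group_id = paste0("n", n, "_", seq_len(ncol(combos))),
    n = n,
    members = lapply(seq_len(ncol(combos)), function(i) combos[, i])
  )
}

# Membership indicator matrix (plants x groups) for a members list-column.
membership_matrix <- function(m, members) {
  P <- matrix(0, nrow(m), length(members), dimnames = list(rownames(m), NULL))
  rows <- match_plants(m, unlist(members))
  cols <- rep(seq_along(members), lengths(members))
  P[cbind(rows, cols)] <- 1
  P
}

# Per-edge tip-membership table used to vectorise Faith PD over many
# leaf-set unions at once: edge e belongs to the spanning subtree of set S
# iff 0 < |tips below e  intersect  S| < |S|.
edge_tip_table <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tr$Nnode
  below <- matrix(0, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    below[p, ] <- below[p, ] + below[ch, ]
  }
  list(E = below[tr$edge[, 2], , drop = FALSE], len = tr$edge.length,
       tips = tr$tip.label)
}

# Faith PD for many host-set columns at once (hosts: fungi x groups 0/1).
faith_pd_many <- function(ett, hosts) {
  sizes <- colSums(hosts)
  cnt <- ett$E %*% hosts
  inside <- (cnt > 0) & sweep(cnt, 2, sizes, "<")
  as.numeric(crossprod(ett$len, inside))
}

#' Classify groups by shared sampling location
#'
#' A group is "same location" iff there exists a single locality at which
#' every member species was sampled (a species may occur at several
#' localities).
#'
#' @param groups A tibble with a `members` list-column (see
#'   [enumerate_groups()]), or a single character vector of plant ids.
#' @param metadata Metadata tibble with `plant_id` and `locality` columns.
#' @return Logical vector, one element per group.
#' @export
classify_location <- function(groups, metadata) {
  members <- if (is.character(groups)) list(groups) else groups$members
  ids <- sort(unique(unlist(members)))
  unknown <- setdiff(ids, metadata$plant_id)
  if (length(unknown)) abort(paste0("species missing from metadata: ", paste(unknown, collapse = ", ")))
  locs <- sort(unique(metadata$locality))
  L <- matrix(0, length(locs), length(ids), dimnames = list(locs, ids))
  keep <- metadata$plant_id %in% ids
  L[cbind(match(metadata$locality[keep], locs), match(metadata$plant_id[keep], ids))] <- 1
  P <- matrix(0, length(ids), length(members))
  P[cbind(match(unlist(members), ids), rep(seq_along(members), lengths(members)))] <- 1
  sizes <- colSums(P)
  covered <- L %*% P  # localities x groups: members of the group present there
  out <- colSums(sweep(covered, 2, sizes, "==")) > 0
  if (is.character(groups)) out[[1]] else unname(out)
}

#' Sampling-effort covariates of plant groups
#'
#' For each group: the total number of specimens sampled over its member
#' species, the number of distinct OTUs in the pooled host set, and the
#' Herfindahl concentration index of specimens among members
#' (sum of squared specimen shares; 1/s for s equally sampled members,
#' 1 for a single member).
#'
#' @inheritParams classify_location
#' @param incidence Incidence tibble or matrix.
#' @return A tibble with `total_specimens`, `total_otus`, `herfindahl`.
#' @export
group_covariates <- function(groups, incidence, metadata) {
  members <- if (is.character(groups)) list(groups) else groups$members
  m <- incidence_matrix(incidence)
  spec <- metadata |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::summarise(n_specimens = sum(.data$n_specimens), .groups = "drop")
  s <- setNames(spec$n_specimens, spec$plant_id)
  missing <- setdiff(unique(unlist(members)), names(s))
  if (length(missing)) abort(paste0("species missing from metadata: ", paste(missing, collapse = ", ")))
  P <- membership_matrix(m, members)
  sv <- s[rownames(m)]
  totals <- as.numeric(crossprod(sv, P))
  herf <- colSums((P * sv)^2) / totals^2
  otus <- colSums((t(m + 0) %*% P) > 0)
  tibble::tibble(
    total_specimens = as.integer(totals),
    total_otus = as.integer(otus),
    herfindahl = herf
  )
}

#' Build a fully annotated group ensemble of one size
#'
#' Enumerates every group of `n` species, computes the combined PD of the
#' pooled host set, the group overlap, sampling covariates and the
#' same-location flag for each, appends any observed communities of the
#' same size, and min-max scales PD and overlap within the generated
#' ensemble's range.
#'
#' @param tree Fungal host phylogeny.
#' @param incidence Incidence tibble or matrix.
#' @param metadata Metadata tibble (`plant_id`, `locality`, `n_specimens`).
#' @param n Group size.
#' @param communities Optional tibble (`community_id`, `plant_id`); only
#'   communities with exactly `n` members are appended, with provenance
#'   `"observed"`, and are scaled against the generated ensemble.
#' @return A tibble of group records (one row per group).
#' @export
build_ensemble <- function(tree, incidence, metadata, n, communities = NULL) {
  m <- incidence_matrix(incidence)
  groups <- enumerate_groups(rownames(m), n)
  groups$provenance <- "generated"
  if (!is.null(communities)) {
    obs <- communities |>
      dplyr::group_by(.data$community_id) |>
      dplyr::summarise(members = list(sort(unique(.data$plant_id))), .groups = "drop") |>
      dplyr::filter(lengths(.data$members) == n)
    if (nrow(obs) > 0) {
      groups <- dplyr::bind_rows(groups, tibble::tibble(
        group_id = obs$community_id, n = as.integer(n),
        members = obs$members, provenance = "observed"
      ))
    }
  }

  P <- membership_matrix(m, groups$members)
  ett <- edge_tip_table(tree)
  otu_order <- match(colnames(m), ett$tips)
  if (anyNA(otu_order)) {
    abort("incidence contains OTUs absent from the tree; run cross_validate()")
  }
  # pooled host sets, aligned to the tree's tip table
  hosts_m <- (t(m + 0) %*% P) > 0
  hosts <- matrix(0, length(ett$tips), ncol(P))
  hosts[otu_order, ] <- hosts_m + 0
  groups$combined_pd <- faith_pd_many(ett, hosts)

  # mean pairwise min-overlap via the quadratic form of the similarity matrix
  O <- pairwise_matrix(m, "overlap")
  diag(O) <- 0
  pair_sums <- colSums(P * (O %*% P)) / 2
  groups$overlap <- pair_sums / choose(n, 2)

  groups <- dplyr::bind_cols(groups, group_covariates(groups, m, metadata))
  groups$same_location <- classify_location(groups, metadata)
  scale_within_ensemble(groups)
}

#' Min-max scale group metrics within a same-size ensemble
#'
#' Adds `scaled_pd` and `scaled_overlap`, each `(raw - min) / (max - min)`
#' with the range taken over the GENERATED groups of the ensemble; observed
#' communities are scaled against that same range. A degenerate range
#' (max == min) yields `NA` for that metric.
#'
#' @param ensemble A tibble of group records with `combined_pd`, `overlap`
#'   and `provenance` columns (a single size).
#' @return The ensemble with `scaled_pd` and `scaled_overlap` columns.
#' @export
scale_within_ensemble <- function(ensemble) {
  if (length(unique(ensemble$n)) > 1) abort("ensemble must contain a single group size")
  gen <- ensemble[ensemble$provenance == "generated", ]
  if (nrow(gen) == 0) abort("ensemble has no generated groups to define the scaling range")
  rescale <- function(x, ref) {
    rng <- range(ref)
    if (diff(rng) <= 1e-12 * max(1, abs(rng[2]))) return(rep(NA_real_, length(x)))
    (x - rng[1]) / diff(rng)
  }
  ensemble$scaled_pd <- rescale(ensemble$combined_pd, gen$combined_pd)
  ensemble$scaled_overlap <- rescale(ensemble$overlap, gen$overlap)
  ensemble
}
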
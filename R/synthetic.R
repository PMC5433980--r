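# Synthetic fungal trees, plant-fungus incidence, metadata and communities
# with the statistical structure the analysis assumes: a fixed fungal pool,
# locality-structured host sharing, heavily skewed host counts, and a few
# co-occurring communities, so every pipeline stage is testable without
# field data.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a location-structured mycoheterotroph survey: 20 plant
#' species, 138 fungal OTUs, host counts spanning 2-42 per species
#' (log-uniform, matching the heavy skew of such counts), 15 localities of
#' which 9 host more than one species, and observed communities of sizes
#' 2, 2, 3, 3, 3, 5.
#'
#' @param seed Integer master seed; all randomness derives from it through
#'   a documented splitting scheme, so any sub-generator is independently
#'   reproducible.
#' @param n_fungi Number of fungal OTUs (tree leaves).
#' @param n_plants Number of plant species.
#' @param n_localities Number of sampling localities.
#' @param multi_species_localities How many localities host >= 2 species.
#' @param host_count_range Length-2 integer range of hosts per species.
#' @param tree_model `"yule"` (pure birth, default) or `"coalescent"`;
#'   both yield ultrametric trees, rescaled to unit depth.
#' @param locality_pool_size Number of OTUs in each locality's fungal pool.
#' @param pool_sharing Probability, per host draw, that a species draws
#'   from its locality pool rather than from the full OTU set. Near 1,
#'   species sharing a locality share hosts; at 0, location carries no
#'   signal.
#' @param specimens_per_species_range Range of specimens per plant x
#'   locality record.
#' @param community_sizes Integer vector of observed-community sizes.
#' @param multi_species_counts Species richness of each multi-species
#'   locality (length `multi_species_localities`, entries >= 2). The
#'   default `c(6, 6, 5, 4, 2, 2, 2, 2, 2)` mirrors the richness profile
#'   of a multi-locality mycoheterotroph survey, where the richest sites
#'   hold four to six co-occurring species.
#' @param clumped_pools If `TRUE`, locality pools are drawn
#'   phylogenetically clumped (a random clade is over-represented) instead
#'   of uniformly.
#' @return A list of class `myco_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_fungi = 138,
                             n_plants = 20,
                             n_localities = 15,
                             multi_species_localities = 9,
                             host_count_range = c(2L, 42L),
                             tree_model = c("yule", "coalescent"),
                             locality_pool_size = 45,
                             pool_sharing = 0.9,
                             specimens_per_species_range = c(1L, 10L),
                             community_sizes = c(2L, 2L, 3L, 3L, 3L, 5L),
                             multi_species_counts = c(6L, 6L, 5L, 4L, 2L, 2L, 2L, 2L, 2L),
                             clumped_pools = FALSE) {
  tree_model <- match.arg(tree_model)
  cfg <- list(seed = as.integer(seed), n_fungi = as.integer(n_fungi),
              n_plants = as.integer(n_plants), n_localities = as.integer(n_localities),
              multi_species_localities = as.integer(multi_species_localities),
              host_count_range = as.integer(host_count_range), tree_model = tree_model,
              locality_pool_size = as.integer(locality_pool_size),
              pool_sharing = as.numeric(pool_sharing),
              specimens_per_species_range = as.integer(specimens_per_species_range),
              community_sizes = sort(as.integer(community_sizes)),
              multi_species_counts = sort(as.integer(multi_species_counts), decreasing = TRUE),
              clumped_pools = isTRUE(clumped_pools))
  with(cfg, {
    if (n_fungi < 2 || n_plants < 2 || n_localities < 1) abort("counts must be positive")
    if (multi_species_localities > n_localities) abort("more multi-species localities than localities")
    if (length(host_count_range) != 2 || host_count_range[1] < 1 || host_count_range[2] > n_fungi ||
        host_count_range[1] > host_count_range[2]) {
      abort("host_count_range must lie within [1, n_fungi]")
    }
    if (pool_sharing < 0 || pool_sharing > 1) abort("pool_sharing must be in [0, 1]")
    if (locality_pool_size < 1 || locality_pool_size > n_fungi) abort("locality_pool_size out of range")
    if (pool_sharing == 1 && locality_pool_size < host_count_range[2]) {
      abort("infeasible config: locality pool smaller than the largest host count with pool_sharing = 1")
    }
    if (any(community_sizes < 2) || max(community_sizes) > n_plants) abort("bad community sizes")
    if (length(multi_species_counts) != multi_species_localities) {
      abort("multi_species_counts must have one entry per multi-species locality")
    }
    if (any(multi_species_counts < 2) || any(multi_species_counts > n_plants)) {
      abort("multi_species_counts entries must lie in [2, n_plants]")
    }
    if (multi_species_localities > 0 && max(multi_species_counts) < max(community_sizes)) {
      abort("no locality is rich enough for the largest community")
    }
  })
  structure(cfg, class = "myco_config")
}

#' @export
print.myco_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic survey config: %d plants, %d fungi, %d localities ",
                     "(%d multi-species), hosts %d-%d, pool %d, sharing %.2f, seed %d\n"),
              x$n_plants, x$n_fungi, x$n_localities, x$multi_species_localities,
              x$host_count_range[1], x$host_count_range[2], x$locality_pool_size,
              x$pool_sharing, x$seed))
  invisible(x)
}

config_seeds <- function(cfg) {
  split_seed(cfg$seed, c("host_tree", "plant_tree", "localities", "hosts",
                         "specimens", "communities"))
}

simulate_ultrametric <- function(n, model, labels) {
  tr <- if (model == "coalescent") ape::rcoal(n) else ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- labels
  tr
}

#' Generate a random ultrametric fungal host tree
#'
#' Pure-birth (Yule) by default, rescaled to unit depth, with leaves
#' labelled `OTU_001`, `OTU_002`, ... Reproducible from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `phylo` object with `config$n_fungi` leaves.
#' @export
generate_tree <- function(config) {
  stopifnot(inherits(config, "myco_config"))
  seeds <- config_seeds(config)
  withr::with_seed(seeds[["host_tree"]], {
    simulate_ultrametric(config$n_fungi, config$tree_model,
                         sprintf("OTU_%03d", seq_len(config$n_fungi)))
  })
}

# Species -> locality assignment guaranteeing: every locality hosts >= 1
# species, exactly `multi_species_localities` host >= 2, every species has
# >= 1 locality, and for each requested community size some locality holds
# enough species.
assign_localities <- function(cfg) {
  plants <- sprintf("plant_%02d", seq_len(cfg$n_plants))
  locs <- sprintf("loc_%02d", seq_len(cfg$n_localities))
  multi <- sample(locs, cfg$multi_species_localities)
  single <- setdiff(locs, multi)
  target <- setNames(rep(1L, cfg$n_localities), locs)
  target[multi] <- cfg$multi_species_counts

  occupants <- setNames(vector("list", cfg$n_localities), locs)
  sp <- sample(plants)  # shuffled; first pass seeds every locality once
  first <- c(multi, single)
  for (i in seq_along(first)) {
    occupants[[first[i]]] <- sp[((i - 1) %% length(sp)) + 1]
  }
  leftover <- setdiff(sp, unlist(occupants))
  for (s in leftover) {
    cap <- target - lengths(occupants)
    open <- names(cap)[cap > 0 & !vapply(occupants, function(o) s %in% o, logical(1))]
    if (!length(open)) open <- multi[!vapply(occupants[multi], function(o) s %in% o, logical(1))]
    pick <- sample(open, 1)
    occupants[[pick]] <- c(occupants[[pick]], s)
  }
  for (l in locs) {
    while (length(occupants[[l]]) < target[l]) {
      pool <- setdiff(plants, occupants[[l]])
      occupants[[l]] <- c(occupants[[l]], sample(pool, 1))
    }
  }
  tibble::tibble(
    locality = rep(locs, lengths(occupants)),
    plant_id = unlist(occupants),
    multi = rep(locs %in% multi, lengths(occupants))
  )
}

#' Generate a full synthetic dataset
#'
#' Draws the fungal and plant phylogenies, gives each locality a random
#' fungal pool, assigns species to localities, draws each species' host
#' set (log-uniform size; each host taken from the species' locality pool
#' with probability `pool_sharing`, otherwise from the full OTU set),
#' fills in specimen counts, and samples observed co-occurring communities
#' from single localities with the configured size multiset.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `myco_dataset`: `host_tree`, `plant_tree`,
#'   `incidence`, `metadata`, `communities`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "myco_config"))
  seeds <- config_seeds(config)
  host_tree <- generate_tree(config)
  plants <- sprintf("plant_%02d", seq_len(config$n_plants))
  plant_tree <- withr::with_seed(seeds[["plant_tree"]], {
    simulate_ultrametric(config$n_plants, "yule", plants)
  })

  assign <- withr::with_seed(seeds[["localities"]], {
    a <- assign_localities(config)
    pools <- lapply(seq_len(config$n_localities), function(i) {
      if (config$clumped_pools) {
        # over-represent a random clade in this locality's pool
        node <- sample(seq_len(host_tree$Nnode), 1) + config$n_fungi
        clade <- ape::extract.clade(host_tree, node)$tip.label
        take <- min(length(clade), ceiling(config$locality_pool_size / 2))
        rest <- setdiff(host_tree$tip.label, clade)
        c(sample(clade, take), sample(rest, config$locality_pool_size - take))
      } else {
        sample(host_tree$tip.label, config$locality_pool_size)
      }
    })
    names(pools) <- sprintf("loc_%02d", seq_len(config$n_localities))
    list(assign = a, pools = pools)
  })

  families <- c("Burmanniaceae", "Gentianaceae", "Triuridaceae")
  fam_of <- withr::with_seed(seeds[["specimens"]], {
    setNames(sample(families, config$n_plants, replace = TRUE), plants)
  })

  inc <- withr::with_seed(seeds[["hosts"]], {
    lo <- log(config$host_count_range[1]); hi <- log(config$host_count_range[2])
    m <- matrix(FALSE, config$n_plants, config$n_fungi,
                dimnames = list(plants, host_tree$tip.label))
    for (s in plants) {
      d <- as.integer(round(exp(runif(1, lo, hi))))
      d <- max(config$host_count_range[1], min(config$host_count_range[2], d))
      my_locs <- assign$assign$locality[assign$assign$plant_id == s]
      # hosts are acquired population by population: each locality's
      # specimens sample that locality's fungal pool, so co-occurring
      # species share hosts through the pool they both tap
      n_pool <- rbinom(1, d, config$pool_sharing)
      per_loc <- if (n_pool > 0) {
        tabulate(sample.int(length(my_locs), n_pool, replace = TRUE),
                 nbins = length(my_locs))
      } else rep(0L, length(my_locs))
      hosts <- character(0)
      for (li in seq_along(my_locs)) {
        pool <- assign$pools[[my_locs[li]]]
        avail <- setdiff(pool, hosts)
        hosts <- c(hosts, sample(avail, min(per_loc[li], length(avail))))
      }
      if (length(hosts) < d) {
        outside <- setdiff(host_tree$tip.label, hosts)
        hosts <- c(hosts, sample(outside, d - length(hosts)))
      }
      m[s, hosts] <- TRUE
    }
    m
  })

  metadata <- withr::with_seed(seeds[["specimens"]] + 1L, {
    assign$assign |>
      dplyr::mutate(
        family = unname(fam_of[.data$plant_id]),
        n_specimens = sample(seq(config$specimens_per_species_range[1],
                                 config$specimens_per_species_range[2]),
                             dplyr::n(), replace = TRUE)
      ) |>
      dplyr::select("plant_id", "family", "locality", "n_specimens") |>
      dplyr::arrange(.data$plant_id, .data$locality)
  })

  communities <- withr::with_seed(seeds[["communities"]], {
    occ <- split(assign$assign$plant_id, assign$assign$locality)
    sizes <- sort(config$community_sizes, decreasing = TRUE)
    used <- character(0)
    rows <- list()
    for (i in seq_along(sizes)) {
      s <- sizes[i]
      ok <- names(occ)[lengths(occ) >= s]
      fresh <- setdiff(ok, used)
      loc <- if (length(fresh)) sample(fresh, 1) else sample(ok, 1)
      used <- c(used, loc)
      rows[[i]] <- tibble::tibble(
        community_id = sprintf("comm_%02d", i),
        plant_id = sort(sample(occ[[loc]], s))
      )
    }
    dplyr::bind_rows(rows)
  })

  incidence <- dplyr::bind_cols(
    tibble::tibble(plant_id = rownames(inc)),
    tibble::as_tibble(as.data.frame(inc + 0L), .name_repair = "minimal")
  )
  structure(list(host_tree = host_tree, plant_tree = plant_tree,
                 incidence = incidence, metadata = metadata,
                 communities = communities, config = config),
            class = "myco_dataset")
}

#' @export
print.myco_dataset <- function(x, ...) {
  d <- host_counts(x$incidence)
  cat(sprintf("synthetic dataset: %d plants x %d fungi, hosts per plant %d-%d, %d localities, %d communities\n",
              nrow(x$incidence), ncol(x$incidence) - 1, min(d), max(d),
              length(unique(x$metadata$locality)),
              length(unique(x$communities$community_id))))
  invisible(x)
}

#' Write a synthetic dataset as a plain-text fixture
#'
#' Emits `host_tree.nwk`, `plant_tree.nwk`, `incidence.tsv`,
#' `metadata.tsv` and `communities.tsv`, each readable by the package's
#' readers and round-trip stable.
#'
#' @param dataset A `myco_dataset` from [generate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "myco_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    host_tree = file.path(out_dir, "host_tree.nwk"),
    plant_tree = file.path(out_dir, "plant_tree.nwk"),
    incidence = file.path(out_dir, "incidence.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    communities = file.path(out_dir, "communities.tsv")
  )
  write_host_tree(dataset$host_tree, paths[["host_tree"]])
  write_host_tree(dataset$plant_tree, paths[["plant_tree"]])
  write_incidence(dataset$incidence, paths[["incidence"]])
  readr::write_tsv(dataset$metadata, paths[["metadata"]], progress = FALSE)
  readr::write_tsv(dataset$communities, paths[["communities"]], progress = FALSE)
  invisible(paths)
}

#' Read a fixture directory back into a dataset list
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with `host_tree`, `plant_tree` (if present), `incidence`,
#'   `metadata`, `communities`.
#' @export
read_fixture <- function(dir) {
  plant_path <- file.path(dir, "plant_tree.nwk")
  comm_path <- file.path(dir, "communities.tsv")
  list(
    host_tree = read_host_tree(file.path(dir, "host_tree.nwk")),
    plant_tree = if (file.exists(plant_path)) read_host_tree(plant_path) else NULL,
    incidence = read_incidence(file.path(dir, "incidence.tsv")),
    metadata = read_plant_metadata(file.path(dir, "metadata.tsv")),
    communities = if (file.exists(comm_path)) read_communities(comm_path) else NULL
  )
}
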
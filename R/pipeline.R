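# End-to-end orchestration: per-plant scaled PD, Mantel phylogenetic-signal
# tests, group ensembles with scaling, correlation inference and
# same-location comparisons, returned as one tidy report object.

#' Run the full diversity-overlap analysis
#'
#' Composes the whole pipeline on one dataset: per-plant Faith PD with
#' exact equal-size normalisation; permutation Mantel tests of plant
#' phylogenetic distance against host-count, Bray-Curtis and (1 -
#' min-overlap) dissimilarities, globally and within each locality hosting
#' at least three species; exhaustive group ensembles for each requested
#' size with min-max scaling and observed-community scaling; Pearson and
#' partial Pearson correlations between scaled PD and scaled overlap (per
#' size, pooled, and across observed communities); and Welch comparisons
#' of scaled PD and scaled overlap between same-location and
#' mixed-location groups.
#'
#' @param host_tree Fungal host phylogeny (`phylo`).
#' @param incidence Plant x fungus incidence tibble or matrix.
#' @param metadata Metadata tibble (`plant_id`, `family`, `locality`,
#'   `n_specimens`).
#' @param communities Optional observed-communities tibble
#'   (`community_id`, `plant_id`).
#' @param plant_tree Optional plant phylogeny; Mantel stages are skipped
#'   (with a note in `meta`) when absent.
#' @param group_sizes Integer vector of ensemble sizes (default 2:5).
#' @param n_perm Mantel permutations (default 10000).
#' @param seed Integer seed governing all permutation draws.
#' @return An object of class `myco_report`; see [report_tables()].
#' @export
run_analysis <- function(host_tree, incidence, metadata, communities = NULL,
                         plant_tree = NULL, group_sizes = 2:5,
                         n_perm = 10000, seed = 1) {
  check_tree(host_tree)
  m <- incidence_matrix(incidence)
  report <- cross_validate(host_tree, m, metadata, communities)
  if (nrow(report) > 0) {
    abort(paste0("inputs failed cross-validation: ",
                 paste(paste(report$check, report$id, sep = ":"), collapse = "; ")))
  }
  seeds <- split_seed(seed, c("mantel", "reserved"))
  plants <- rownames(m)
  d <- host_counts(m)

  # --- per-plant scaled PD ------------------------------------------------
  ext <- pd_extremes(host_tree, unique(d))
  pd_obs <- vapply(plants, function(p) faith_pd(host_tree, colnames(m)[m[p, ]]), numeric(1))
  per_plant <- tibble::tibble(plant_id = plants, d = as.integer(d)) |>
    dplyr::left_join(ext, by = c(d = "k")) |>
    dplyr::mutate(
      pd = pd_obs,
      scaled_pd = dplyr::if_else(.data$pd_max - .data$pd_min > 1e-12,
                                 (pd_obs - .data$pd_min) / (.data$pd_max - .data$pd_min),
                                 NA_real_)
    ) |>
    dplyr::select("plant_id", "d", "pd", "pd_min", "pd_max", "scaled_pd")

  # --- Mantel phylogenetic-signal tests -----------------------------------
  mantel_tbl <- tibble::tibble()
  mantel_note <- NULL
  if (!is.null(plant_tree)) {
    check_tree(plant_tree)
    run_set <- function(ids, scope) {
      sub <- m[ids, , drop = FALSE]
      pdist <- phylo_distance_matrix(plant_tree, ids)
      mats <- list(
        host_count = pairwise_matrix(sub, "count"),
        bray_curtis = pairwise_matrix(sub, "bray_curtis"),
        overlap = 1 - pairwise_matrix(sub, "overlap")
      )
      purrr::imap_dfr(mats, function(mm, nm) {
        res <- mantel_test(pdist, mm, n_perm = n_perm, seed = seeds[["mantel"]])
        dplyr::bind_cols(tibble::tibble(scope = scope, measure = nm), tidy(res))
      })
    }
    mantel_tbl <- run_set(plants, "global")
    by_loc <- split(metadata$plant_id, metadata$locality)
    for (loc in names(by_loc)) {
      ids <- intersect(plants, unique(by_loc[[loc]]))
      if (length(ids) >= 3) mantel_tbl <- dplyr::bind_rows(mantel_tbl, run_set(ids, loc))
    }
  } else {
    mantel_note <- "no plant tree supplied; Mantel phylogenetic-signal tests skipped"
  }

  # --- ensembles, correlations, location comparisons ----------------------
  ensembles <- purrr::map_dfr(group_sizes, function(nn) {
    build_ensemble(host_tree, m, metadata, nn, communities)
  })
  gen <- ensembles[ensembles$provenance == "generated", ]
  obs <- ensembles[ensembles$provenance == "observed", ]

  cor_rows <- list()
  for (nn in group_sizes) {
    g <- gen[gen$n == nn, ]
    raw <- pearson_cor(g$scaled_pd, g$scaled_overlap)
    part <- partial_pearson(g$scaled_pd, g$scaled_overlap,
                            g[, c("total_specimens", "total_otus", "herfindahl")])
    cor_rows <- c(cor_rows, list(
      dplyr::bind_cols(tibble::tibble(scope = paste0("size_", nn), type = "raw"), tidy(raw)),
      dplyr::bind_cols(tibble::tibble(scope = paste0("size_", nn), type = "partial"), tidy(part))
    ))
  }
  pooled <- pearson_cor(gen$scaled_pd, gen$scaled_overlap)
  cor_rows <- c(cor_rows, list(
    dplyr::bind_cols(tibble::tibble(scope = "pooled", type = "raw"), tidy(pooled))
  ))
  if (nrow(obs) >= 3) {
    oc <- pearson_cor(obs$scaled_pd, obs$scaled_overlap)
    cor_rows <- c(cor_rows, list(
      dplyr::bind_cols(tibble::tibble(scope = "observed", type = "raw"), tidy(oc))
    ))
  }
  correlations <- dplyr::bind_rows(cor_rows)

  loc_rows <- list()
  for (metric in c("scaled_pd", "scaled_overlap")) {
    for (nn in group_sizes) {
      g <- gen[gen$n == nn, ]
      a <- g[[metric]][g$same_location]
      b <- g[[metric]][!g$same_location]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) >= 2 && length(b) >= 2) {
        tt <- tidy(welch_t_test(a, b))
        loc_rows <- c(loc_rows, list(dplyr::bind_cols(
          tibble::tibble(metric = metric, n = nn), tt
        )))
      }
    }
  }
  location_tests <- if (length(loc_rows)) {
    dplyr::bind_rows(loc_rows) |>
      dplyr::rename(mean_same = "mean_a", mean_diff = "mean_b",
                    n_same = "n_a", n_diff = "n_b")
  } else {
    tibble::tibble(metric = character(), n = integer())
  }

  structure(list(
    per_plant = per_plant,
    mantel = mantel_tbl,
    groups = ensembles,
    correlations = correlations,
    location_tests = location_tests,
    meta = list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                group_sizes = as.integer(group_sizes),
                n_plants = length(plants), n_fungi = ncol(m),
                notes = mantel_note)
  ), class = "myco_report")
}

#' @export
print.myco_report <- function(x, ...) {
  cat(sprintf("diversity-overlap analysis: %d plants, %d fungi\n",
              x$meta$n_plants, x$meta$n_fungi))
  cat(sprintf("  group ensembles: sizes %s, %d groups (%d observed communities)\n",
              paste(x$meta$group_sizes, collapse = ","), nrow(x$groups),
              sum(x$groups$provenance == "observed")))
  pooled <- x$correlations[x$correlations$scope == "pooled", ]
  if (nrow(pooled)) {
    cat(sprintf("  pooled scaled PD ~ scaled overlap: r = %.3f, df = %d, p = %.3g\n",
                pooled$r[1], pooled$df[1], pooled$p.value[1]))
  }
  if (nrow(x$mantel)) {
    g <- x$mantel[x$mantel$scope == "global", ]
    cat(sprintf("  global Mantel (%s): r = %s\n", paste(g$measure, collapse = "/"),
                paste(sprintf("%.3f", g$r), collapse = "/")))
  } else if (!is.null(x$meta$notes)) cat("  note:", x$meta$notes, "\n")
  invisible(x)
}

#' Export a report as TSV tables plus a JSON summary
#'
#' Writes `per_plant.tsv`, `mantel.tsv`, `groups.tsv` (members collapsed
#' with `;`), `correlations.tsv`, `location_tests.tsv` and `summary.json`.
#'
#' @param report A `myco_report` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
report_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "myco_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups_flat <- report$groups |>
    dplyr::mutate(members = vapply(.data$members, paste, character(1), collapse = ";"))
  paths <- c(per_plant = "per_plant.tsv", mantel = "mantel.tsv", groups = "groups.tsv",
             correlations = "correlations.tsv", location_tests = "location_tests.tsv",
             summary = "summary.json")
  paths <- setNames(file.path(out_dir, paths), names(paths))
  readr::write_tsv(report$per_plant, paths[["per_plant"]], progress = FALSE)
  readr::write_tsv(report$mantel, paths[["mantel"]], progress = FALSE)
  readr::write_tsv(groups_flat, paths[["groups"]], progress = FALSE)
  readr::write_tsv(report$correlations, paths[["correlations"]], progress = FALSE)
  readr::write_tsv(report$location_tests, paths[["location_tests"]], progress = FALSE)
  summary <- list(
    meta = report$meta,
    per_plant = report$per_plant,
    mantel = report$mantel,
    correlations = report$correlations,
    location_tests = report$location_tests
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}
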
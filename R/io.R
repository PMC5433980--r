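# Readers/writers for the formats the pipeline touches, with validation.
#
# TSV schemas (UTF-8, tab-delimited, header row required):
#   incidence (wide): plant_id, then one 0/1 column per fungal OTU
#   metadata:         plant_id, family, locality, n_specimens
#                     (one row per plant x locality)
#   communities:      community_id, plant_id (one row per member)
#   long records:     specimen_id, plant_id, locality, otu [, family]

#' Read a fungal host phylogeny from a Newick file
#'
#' Branch lengths are mandatory on all non-root edges (PD is undefined
#' without them); quoted labels are accepted and `[...]` comments stripped;
#' unary internal nodes are collapsed.
#'
#' @param path Path to a Newick file.
#' @return A validated `phylo` object.
#' @export
read_host_tree <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt_clean <- gsub("\\[[^]]*\\]", "", txt)
  chars <- strsplit(txt_clean, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    pos <- if (any(depth < 0)) which(depth < 0)[1] else length(depth)
    abort(paste0("malformed Newick in ", path,
                 ": unbalanced parentheses near character ", pos))
  }
  tree <- tryCatch(ape::read.tree(text = txt_clean),
                   error = function(e) abort(paste0("malformed Newick in ", path, ": ", conditionMessage(e))))
  if (is.null(tree)) abort(paste0("malformed Newick in ", path))
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  tree <- ape::collapse.singles(tree)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    abort(paste0("missing branch lengths in ", path, "; all non-root edges must carry lengths"))
  }
  if (anyNA(tree$edge.length)) abort(paste0("missing branch lengths in ", path))
  if (any(tree$edge.length < 0)) abort(paste0("negative branch lengths in ", path))
  if (any(!nzchar(tree$tip.label))) abort(paste0("empty leaf labels in ", path))
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate leaf label(s) in ", path, ": ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")))
  }
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_host_tree <- function(tree, path) {
  check_tree(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a plant x fungus incidence table (wide TSV)
#'
#' First column is the plant id; remaining columns are fungal OTU ids with
#' 0/1 cells. Every plant must have at least one host.
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble with column `plant_id` followed by 0/1 OTU columns.
#' @export
read_incidence <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       name_repair = "minimal", progress = FALSE)
  if (ncol(x) < 2) abort("incidence file needs a plant-id column plus at least one OTU column")
  ids <- as.character(x[[1]])
  vals <- lapply(x[-1], function(col) suppressWarnings(as.numeric(col)))
  bad <- vapply(vals, function(v) anyNA(v) || !all(v %in% c(0, 1)), logical(1))
  if (any(bad)) {
    abort(paste0("non-binary cells in incidence column(s): ",
                 paste(names(x)[-1][bad], collapse = ", ")))
  }
  out <- tibble::as_tibble(c(list(plant_id = ids), vals), .name_repair = "minimal")
  incidence_matrix(out)  # duplicate-id and row-sum checks
  out
}

#' Write an incidence table to TSV
#'
#' @param incidence Incidence tibble or matrix (see [host_counts()]).
#' @param path Output path.
#' @export
write_incidence <- function(incidence, path) {
  m <- incidence_matrix(incidence)
  out <- tibble::as_tibble(as.data.frame(m + 0L), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(plant_id = rownames(m)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read per-species metadata (TSV)
#'
#' Schema: `plant_id`, `family`, `locality`, `n_specimens`, one row per
#' plant x locality record; a species sampled at several localities has
#' several rows.
#'
#' @param path Path to a tab-delimited file.
#' @return A validated tibble.
#' @export
read_plant_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    plant_id = readr::col_character(), family = readr::col_character(),
    locality = readr::col_character(), n_specimens = readr::col_integer()
  ), progress = FALSE)
  need <- c("plant_id", "family", "locality", "n_specimens")
  if (!all(need %in% names(x))) abort(paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  if (anyNA(x$n_specimens) || any(x$n_specimens < 1)) abort("n_specimens must be positive integers")
  if (anyDuplicated(x[, c("plant_id", "locality")])) abort("duplicated plant x locality rows in metadata")
  x
}

#' Read observed community definitions (TSV)
#'
#' Schema: `community_id`, `plant_id`, one row per member. Every community
#' must have at least two distinct members.
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble with one row per community member.
#' @export
read_communities <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    community_id = readr::col_character(), plant_id = readr::col_character()
  ), progress = FALSE)
  if (!all(c("community_id", "plant_id") %in% names(x))) {
    abort("communities file must have columns: community_id, plant_id")
  }
  if (anyDuplicated(x)) abort("duplicated community membership rows")
  sizes <- table(x$community_id)
  if (any(sizes < 2)) {
    abort(paste0("communities with fewer than two members: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  x
}

#' Collapse long-format specimen records to incidence plus metadata
#'
#' Accepts one row per (specimen, OTU) detection with columns
#' `specimen_id`, `plant_id`, `locality`, `otu` and optional `family`, as
#' sequencing output is naturally tabulated. Presence of an OTU in any
#' specimen of a species marks the species-level incidence; specimen counts
#' per plant x locality populate the metadata.
#'
#' @param path Path to a tab-delimited long-format file.
#' @return A list with elements `incidence` and `metadata`.
#' @export
read_long_records <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  need <- c("specimen_id", "plant_id", "locality", "otu")
  if (!all(need %in% names(x))) abort(paste0("long records must have columns: ", paste(need, collapse = ", ")))
  inc <- x |>
    dplyr::distinct(.data$plant_id, .data$otu) |>
    dplyr::mutate(present = 1) |>
    tidyr::pivot_wider(names_from = "otu", values_from = "present", values_fill = 0) |>
    dplyr::arrange(.data$plant_id)
  meta <- x |>
    dplyr::distinct(.data$specimen_id, .data$plant_id, .data$locality,
                    family = if ("family" %in% names(x)) .data$family else NA_character_) |>
    dplyr::count(.data$plant_id, .data$family, .data$locality, name = "n_specimens") |>
    dplyr::select("plant_id", "family", "locality", "n_specimens")
  list(incidence = inc, metadata = meta)
}

#' Cross-validate the four pipeline inputs
#'
#' Report-only consistency check: lists fungus ids in the incidence that are
#' not tree leaves, plants without metadata, and community members missing
#' from the incidence. An empty report means the dataset is admissible.
#'
#' @param tree Fungal host phylogeny.
#' @param incidence Incidence tibble or matrix.
#' @param metadata Metadata tibble (see [read_plant_metadata()]).
#' @param communities Optional communities tibble.
#' @return A tibble with columns `check`, `id` (zero rows when consistent).
#' @export
cross_validate <- function(tree, incidence, metadata, communities = NULL) {
  m <- incidence_matrix(incidence)
  probs <- list()
  missing_otus <- setdiff(colnames(m), tree$tip.label)
  if (length(missing_otus)) {
    probs <- c(probs, list(tibble::tibble(check = "otu_not_in_tree", id = missing_otus)))
  }
  missing_meta <- setdiff(rownames(m), metadata$plant_id)
  if (length(missing_meta)) {
    probs <- c(probs, list(tibble::tibble(check = "plant_without_metadata", id = missing_meta)))
  }
  extra_meta <- setdiff(metadata$plant_id, rownames(m))
  if (length(extra_meta)) {
    probs <- c(probs, list(tibble::tibble(check = "metadata_without_plant", id = extra_meta)))
  }
  if (!is.null(communities)) {
    missing_comm <- setdiff(unique(communities$plant_id), rownames(m))
    if (length(missing_comm)) {
      probs <- c(probs, list(tibble::tibble(check = "community_member_unknown", id = missing_comm)))
    }
  }
  if (length(probs)) dplyr::bind_rows(probs) else tibble::tibble(check = character(), id = character())
}
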
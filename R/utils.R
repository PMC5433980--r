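# Internal helpers shared across modules.

# Coerce an incidence table (tibble with a leading plant-id column, or a
# named 0/1 matrix) to a logical plants x fungi matrix, validating the
# binary contract along the way.
incidence_matrix <- function(incidence) {
  if (is.matrix(incidence)) {
    m <- incidence
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      abort("incidence matrix must carry plant row names and fungus column names")
    }
  } else {
    incidence <- as.data.frame(incidence)
    if (ncol(incidence) < 2) abort("incidence table needs a plant-id column plus at least one fungus column")
    ids <- as.character(incidence[[1]])
    m <- as.matrix(incidence[, -1, drop = FALSE])
    rownames(m) <- ids
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || !all(m %in% c(0, 1))) abort("incidence cells must all be 0 or 1")
  if (anyDuplicated(rownames(m))) abort("duplicated plant ids in incidence")
  if (anyDuplicated(colnames(m))) abort("duplicated fungus ids in incidence")
  if (any(rownames(m) == "") || any(colnames(m) == "")) abort("empty ids in incidence")
  if (any(rowSums(m) < 1)) {
    abort(paste0("plants with no fungal hosts (all-zero rows): ",
                 paste(rownames(m)[rowSums(m) < 1], collapse = ", ")))
  }
  m > 0
}

# Resolve a vector of plant ids against an incidence matrix, with a clear
# error naming the offenders.
match_plants <- function(m, ids) {
  idx <- match(ids, rownames(m))
  if (anyNA(idx)) abort(paste0("unknown plant id(s): ", paste(ids[is.na(idx)], collapse = ", ")))
  idx
}

upper_tri_vec <- function(m) m[upper.tri(m)]

# Deterministic evaluation under an optional seed; NULL leaves the RNG alone.
with_opt_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Split one user seed into named, independently usable sub-seeds (all < 2^31).
split_seed <- function(seed, names) {
  withr::with_seed(as.integer(seed), {
    setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
  })
}
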
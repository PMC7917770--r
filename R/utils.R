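# Internal helpers shared across modules.

# Convert a wide matrix tibble (id column + one column per sample) to a
# numeric matrix with ids as rownames.
tbl_to_matrix <- function(tbl, id_col = "gene_id") {
  stopifnot(is.data.frame(tbl), id_col %in% names(tbl))
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate values in '%s' column", id_col))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (anyDuplicated(colnames(m))) abort("duplicate sample columns")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_col := rownames(m)), out)
}

# Validate a two-column label table and return labels aligned to `ids`.
aligned_labels <- function(labels, ids, id_col, label_col, allowed) {
  stopifnot(is.data.frame(labels), all(c(id_col, label_col) %in% names(labels)))
  if (anyDuplicated(labels[[id_col]])) abort(sprintf("duplicate '%s' entries", id_col))
  missing <- setdiff(ids, labels[[id_col]])
  if (length(missing) > 0) {
    abort(sprintf("no %s label for: %s", label_col,
                  paste(head(missing, 5), collapse = ", ")))
  }
  lab <- labels[[label_col]][match(ids, labels[[id_col]])]
  bad <- setdiff(unique(lab), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s label(s): %s (expected %s)", label_col,
                  paste(bad, collapse = ", "), paste(allowed, collapse = "/")))
  }
  lab
}

# Deterministic per-generator substream so adding a generator never perturbs
# the draws of the others. Keeps the derived seed inside 32-bit range.
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147480000 + stream * 1000003) %% 2147480000)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("'%s' must be an integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("'%s' must lie in [0, 1]", name))
  }
  as.numeric(x)
}
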
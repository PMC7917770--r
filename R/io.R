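# Readers and writers for the plain-text formats the pipeline consumes:
# TSV matrices (genes as rows, first column gene_id), 6-column BED
# (0-based half-open), GMT gene-set collections and RNK ranked lists.

#' Read / write a gene-by-sample matrix as TSV
#'
#' Genes as rows; the first column is `gene_id`, remaining columns are
#' numeric samples.
#'
#' @param path File path.
#' @param x Matrix tibble to write.
#' @return `read_matrix_tsv()` returns a tibble; `write_matrix_tsv()`
#'   returns `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  names(out)[1] <- "gene_id"
  out
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write 6-column BED interval files
#'
#' Columns chrom, start, end, name, score, strand with 0-based half-open
#' coordinates. `signal_col = "signal"` (the default for peak files) maps
#' the BED score column to/from a `signal` column; promoter files typically
#' use `name_col = "gene_id"` to carry gene labels in column 4.
#'
#' @param path File path.
#' @param x Interval tibble to write.
#' @param name_col,signal_col Tibble column names mapped to BED columns 4
#'   and 5.
#' @return `read_bed()` returns an interval tibble; `write_bed()` returns
#'   `path` invisibly.
#' @export
read_bed <- function(path, name_col = "name", signal_col = "signal") {
  out <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", name_col,
                                       signal_col, "strand"),
                         col_types = "cddcdc", show_col_types = FALSE)
  names(out) <- c("chrom", "start", "end", name_col, signal_col, "strand")
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  out[[signal_col]] <- as.numeric(out[[signal_col]])
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path, name_col = NULL, signal_col = NULL) {
  if (is.null(name_col)) {
    name_col <- if ("gene_id" %in% names(x)) "gene_id" else "name"
  }
  if (is.null(signal_col)) {
    signal_col <- if ("signal" %in% names(x)) "signal" else "score"
  }
  out <- tibble(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if (name_col %in% names(x)) x[[name_col]] else ".",
    score = if (signal_col %in% names(x)) x[[signal_col]] else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' One set per line: name, description, then member gene ids, tab
#' separated.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param description Description field written for each set.
#' @return `read_gmt()` returns a named list of character vectors;
#'   `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line (need name, description, >=1 gene)")
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write RNK ranked lists
#'
#' Two tab-separated columns (gene id, ranking metric), no header.
#'
#' @param path File path.
#' @param ranked Tibble with `gene_id` and `metric`.
#' @return `read_rnk()` returns a tibble with `gene_id` and `metric`;
#'   `write_rnk()` returns `path` invisibly.
#' @export
read_rnk <- function(path) {
  readr::read_tsv(path, col_names = c("gene_id", "metric"),
                  col_types = "cd", show_col_types = FALSE)
}

#' @rdname read_rnk
#' @export
write_rnk <- function(ranked, path) {
  readr::write_tsv(ranked[, c("gene_id", "metric")], path, col_names = FALSE)
  invisible(path)
}
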
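# Stage 1 of the screen: group-averaged dependency scores and the
# dual-threshold selection of target-type-specific susceptibility genes.

#' Average dependency score per gene and cell-line group
#'
#' Computes, for every gene, the average CRISPR dependency score across the
#' target-type cell lines and across all other cell lines. Negative scores
#' mean knockout depletes the cells, so a strongly negative target-group
#' average with a near-zero background average marks a candidate
#' target-specific susceptibility gene. Missing scores (`NA`) are dropped
#' from the averages; genes with fewer than `min_obs` non-missing values in
#' either group are flagged ineligible and excluded from later selection.
#'
#' @param scores Tibble with `gene_id` plus one numeric column per cell
#'   line.
#' @param groups Tibble with `cell_line_id` and `group` in
#'   `{"target","other"}`; both groups must be non-empty.
#' @param summary `"mean"` (the default reading of "average") or
#'   `"median"`.
#' @param min_obs Minimum non-missing observations per group for a gene to
#'   stay eligible (default 1).
#' @return A tibble with `gene_id`, `mean_target`, `mean_other`,
#'   `n_target`, `n_other`, `eligible`.
#' @export
#' @examples
#' dep <- gen_dependency(sim_config(seed = 1, n_genes = 20))
#' group_mean_scores(dep$scores, dep$groups)
group_mean_scores <- function(scores, groups, summary = c("mean", "median"),
                              min_obs = 1L) {
  summary <- match.arg(summary)
  m <- tbl_to_matrix(scores)
  if (nrow(m) == 0 || ncol(m) == 0) abort("empty dependency matrix")
  lab <- aligned_labels(groups, colnames(m), "cell_line_id", "group",
                        c("target", "other"))
  if (!all(c("target", "other") %in% lab)) {
    abort("both 'target' and 'other' groups must have at least one cell line")
  }
  fun <- if (summary == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) median(x, na.rm = TRUE)
  }
  tgt <- m[, lab == "target", drop = FALSE]
  oth <- m[, lab == "other", drop = FALSE]
  n_target <- rowSums(!is.na(tgt))
  n_other <- rowSums(!is.na(oth))
  mean_target <- apply(tgt, 1, fun)
  mean_other <- apply(oth, 1, fun)
  mean_target[n_target == 0] <- NA_real_
  mean_other[n_other == 0] <- NA_real_
  tibble(
    gene_id = rownames(m),
    mean_target = unname(mean_target),
    mean_other = unname(mean_other),
    n_target = unname(as.integer(n_target)),
    n_other = unname(as.integer(n_other)),
    eligible = n_target >= min_obs & n_other >= min_obs
  )
}

#' Dual-threshold selection of susceptibility candidates
#'
#' A gene is selected iff its target-group average score falls below
#' `thr_target` while its background average stays above `thr_other`
#' (defaults -0.5 and -0.2) — strong dependency in the target type only.
#' Both comparisons are strict by default ("below" / "higher than"), so
#' boundary genes are excluded; set `strict = FALSE` to include them.
#'
#' @param means Output of [group_mean_scores()].
#' @param thr_target Upper bound on the target-group average (default -0.5).
#' @param thr_other Lower bound on the background average (default -0.2);
#'   must exceed `thr_target` or the selection region is empty/inverted.
#' @param strict Use strict inequalities (default `TRUE`).
#' @return `means` with a logical `stage1_pass` column; ineligible or
#'   missing-mean genes never pass.
#' @export
select_susceptibility_candidates <- function(means, thr_target = -0.5,
                                             thr_other = -0.2, strict = TRUE) {
  if (thr_target >= thr_other) {
    abort("'thr_target' must be < 'thr_other' (selection region otherwise empty or inverted)")
  }
  cmp_lt <- if (strict) `<` else `<=`
  cmp_gt <- if (strict) `>` else `>=`
  means |>
    mutate(stage1_pass = .data$eligible &
             !is.na(.data$mean_target) & !is.na(.data$mean_other) &
             cmp_lt(.data$mean_target, thr_target) &
             cmp_gt(.data$mean_other, thr_other))
}
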
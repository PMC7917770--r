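# Knockout-versus-control differential expression: median-of-ratios
# normalization, a deliberately simple log-scale Welch test, and the exact
# fold/significance filter. The test is a documented stand-in for a full
# negative-binomial GLM framework; the filter also accepts externally
# computed (gene, log2fc, p) tables so it can sit on top of any engine.

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over genes with nonzero counts in
#' every sample, of that sample's count divided by the gene's geometric
#' mean across samples. Factors are returned raw (no rescaling).
#'
#' @param counts Tibble with `gene_id` plus one non-negative integer column
#'   per sample.
#' @return A tibble with `sample_id` and `size_factor`.
#' @export
#' @examples
#' cts <- gen_counts(sim_config(seed = 1, n_genes = 100))
#' size_factors(cts$counts)
size_factors <- function(counts) {
  m <- tbl_to_matrix(counts)
  if (any(m < 0, na.rm = TRUE)) abort("counts must be >= 0")
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    abort("no gene has nonzero counts in all samples; add a pseudocount upstream")
  }
  lg <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Simple differential-expression test (normalized log-scale Welch t)
#'
#' Counts are divided by [size_factors()], shifted by `pseudocount` and
#' log2-transformed; each gene's two conditions are then compared with a
#' Welch two-sample t-test on the transformed values, and the log2 fold
#' change is the difference of condition means on that scale
#' (knockout minus control). When both groups have zero variance the
#' p-value is 1 for equal means and 0 otherwise, by convention. This is an
#' intentionally simple stand-in for a count-model test; its null
#' calibration is checked by simulation.
#'
#' @param counts Tibble with `gene_id` plus one count column per sample.
#' @param conditions Tibble with `sample_id` and `condition` in
#'   `{"control","knockout"}`; at least two replicates each.
#' @param pseudocount Added before the log transform (default 1).
#' @return A tibble with `gene_id`, `base_mean` (mean normalized count),
#'   `log2_fold_change`, `t_statistic`, `p_value`.
#' @export
de_test <- function(counts, conditions, pseudocount = 1) {
  m <- tbl_to_matrix(counts)
  lab <- aligned_labels(conditions, colnames(m), "sample_id", "condition",
                        c("control", "knockout"))
  n1 <- sum(lab == "control"); n2 <- sum(lab == "knockout")
  if (n1 < 2 || n2 < 2) abort("need >= 2 replicates per condition")
  sf <- size_factors(counts)$size_factor
  norm <- sweep(m, 2, sf, "/")
  lx <- log2(norm + pseudocount)
  a <- lx[, lab == "control", drop = FALSE]
  b <- lx[, lab == "knockout", drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m2 - m1
  tstat <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff == 0, 0, Inf * sign(diff)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), df),
              0)
  p[se2 == 0 & diff == 0] <- 1
  tibble(
    gene_id = rownames(m),
    base_mean = unname(rowMeans(norm)),
    log2_fold_change = unname(diff),
    t_statistic = unname(tstat),
    p_value = unname(p)
  )
}

#' Fold-and-significance filter for differential expression
#'
#' Flags a gene as differentially expressed iff its absolute fold change is
#' at least `min_fold` (inclusive, reading "at least 2-fold") and its
#' p-value is below `max_p` (strict, reading "below 0.01"). Optionally the
#' filter can run on Benjamini-Hochberg adjusted p-values; raw p-values are
#' the default because the rule it implements is stated on raw p.
#'
#' @param results Tibble with `log2_fold_change` and `p_value` columns —
#'   from [de_test()] or any external engine.
#' @param min_fold Minimum linear fold change (default 2).
#' @param max_p Maximum p-value, exclusive (default 0.01).
#' @param adjust Apply BH adjustment before filtering (default `FALSE`).
#' @return `results` with an `is_de` logical column (and `p_adjusted` when
#'   `adjust = TRUE`).
#' @export
de_filter <- function(results, min_fold = 2, max_p = 0.01, adjust = FALSE) {
  if (min_fold <= 0 || max_p <= 0) abort("thresholds must be > 0")
  stopifnot(all(c("log2_fold_change", "p_value") %in% names(results)))
  p <- results$p_value
  if (adjust) {
    p <- stats::p.adjust(p, method = "BH")
    results$p_adjusted <- p
  }
  results |>
    mutate(is_de = abs(.data$log2_fold_change) >= log2(min_fold) & p < max_p)
}
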
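# Stage 2 of the screen: tumor-versus-reference expression enrichment.

#' Tumor-versus-reference expression enrichment per gene
#'
#' Computes group-average TPM in the tumor and reference samples and the
#' fold change between them. The default dialect is a linear-scale fold of
#' group means with a pseudocount,
#' `(mean_tumor + pseudocount) / (mean_reference + pseudocount)`; the
#' `"log2"` dialect instead takes the difference of group means of
#' `log2(TPM + pseudocount)` and reports `fold_change = 2^difference`, so
#' downstream thresholds apply unchanged.
#'
#' @param tpm Tibble with `gene_id` plus one non-negative numeric column per
#'   sample.
#' @param samples Tibble with `sample_id` and `group` in
#'   `{"tumor","reference"}`; both groups must be non-empty.
#' @param pseudocount Non-negative stabiliser (default 1). With
#'   `pseudocount = 0`, genes with zero reference mean get an infinite fold,
#'   flagged via `fold_defined = FALSE` and excluded by
#'   [select_overexpressed()].
#' @param summary `"mean"` (default) or `"median"` group summary.
#' @param scale `"linear"` (default) or `"log2"` fold dialect.
#' @return A tibble with `gene_id`, `mean_tumor_tpm`, `mean_reference_tpm`,
#'   `fold_change`, `fold_defined`.
#' @export
#' @examples
#' ex <- gen_expression(sim_config(seed = 1, n_genes = 20))
#' expression_enrichment(ex$tpm, ex$samples)
expression_enrichment <- function(tpm, samples, pseudocount = 1,
                                  summary = c("mean", "median"),
                                  scale = c("linear", "log2")) {
  summary <- match.arg(summary)
  scale <- match.arg(scale)
  if (pseudocount < 0) abort("'pseudocount' must be >= 0")
  m <- tbl_to_matrix(tpm)
  if (any(m < 0, na.rm = TRUE)) abort("TPM values must be >= 0")
  lab <- aligned_labels(samples, colnames(m), "sample_id", "group",
                        c("tumor", "reference"))
  if (!all(c("tumor", "reference") %in% lab)) {
    abort("both 'tumor' and 'reference' groups must be non-empty")
  }
  fun <- if (summary == "mean") rowMeans else function(x) apply(x, 1, median)
  tum <- fun(m[, lab == "tumor", drop = FALSE])
  ref <- fun(m[, lab == "reference", drop = FALSE])
  if (scale == "linear") {
    num <- tum + pseudocount
    den <- ref + pseudocount
    fold <- ifelse(den > 0, num / den, Inf)
  } else {
    lt <- fun(log2(m[, lab == "tumor", drop = FALSE] + pseudocount))
    lr <- fun(log2(m[, lab == "reference", drop = FALSE] + pseudocount))
    fold <- 2^(lt - lr)
  }
  tibble(
    gene_id = rownames(m),
    mean_tumor_tpm = unname(tum),
    mean_reference_tpm = unname(ref),
    fold_change = unname(fold),
    fold_defined = is.finite(fold)
  )
}

#' Select overexpressed genes by fold and expression thresholds
#'
#' A gene passes iff its tumor/reference fold change exceeds `min_fold` and
#' its tumor-group average TPM exceeds `min_tumor_tpm` (both strict,
#' matching ">3 fold" and "TPM > 10"). Genes with undefined (infinite) fold
#' never pass.
#'
#' @param enrichment Output of [expression_enrichment()].
#' @param min_fold Minimum fold change (default 3).
#' @param min_tumor_tpm Minimum tumor-group average TPM (default 10).
#' @return `enrichment` with a logical `stage2_pass` column.
#' @export
select_overexpressed <- function(enrichment, min_fold = 3, min_tumor_tpm = 10) {
  if (min_fold <= 0 || min_tumor_tpm <= 0) abort("thresholds must be > 0")
  enrichment |>
    mutate(stage2_pass = .data$fold_defined &
             .data$fold_change > min_fold &
             .data$mean_tumor_tpm > min_tumor_tpm)
}
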
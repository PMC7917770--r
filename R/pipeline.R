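# Orchestration of the three-stage susceptibility screen and of the
# integrative promoter-binding / expression-change enrichment analysis.

#' Run the three-stage susceptibility screen
#'
#' Executes, in order: (1) dual-threshold dependency selection
#' ([group_mean_scores()] + [select_susceptibility_candidates()]);
#' (2) tumor-versus-reference expression enrichment
#' ([expression_enrichment()] + [select_overexpressed()]); (3) per-gene
#' hazard ranking ([hazard_screen()]). By default the stages are strictly
#' nested — each filter is evaluated only on the previous stage's passers,
#' so the candidate funnel can only shrink; `nested = FALSE` scores every
#' gene at every stage for exploratory use. A gene is a final candidate iff
#' it passes stages 1-2 and its high/low hazard ratio exceeds `hr_cut` with
#' log-rank p below `p_cut`.
#'
#' @param scores,score_groups Dependency matrix tibble and cell-line group
#'   table (see [group_mean_scores()]).
#' @param tpm,tpm_samples Expression matrix tibble and sample group table
#'   (see [expression_enrichment()]).
#' @param surv Survival tibble (`sample_id`, `time`, `event`, gene
#'   columns).
#' @param thr_target,thr_other Stage-1 thresholds (defaults -0.5 / -0.2).
#' @param min_fold,min_tumor_tpm Stage-2 thresholds (defaults 3 / 10).
#' @param q Stage-3 stratification quantile (default 0.25).
#' @param hr_cut,p_cut Candidate definition: `hr > hr_cut` and
#'   `logrank_p < p_cut` (defaults 1 / 0.05).
#' @param pseudocount Stage-2 fold pseudocount (default 1).
#' @param nested Evaluate each stage only on the previous stage's passers
#'   (default `TRUE`).
#' @return A tibble of class `screen_result`, one row per gene in the
#'   dependency matrix, carrying every stage's statistics, `stage1_pass`,
#'   `stage2_pass`, `stage3_rank` (dense rank by descending hazard ratio
#'   among stage-3 genes) and `candidate`. Funnel counts are available via
#'   [glance()].
#' @export
run_screen <- function(scores, score_groups, tpm, tpm_samples, surv,
                       thr_target = -0.5, thr_other = -0.2,
                       min_fold = 3, min_tumor_tpm = 10, q = 0.25,
                       hr_cut = 1, p_cut = 0.05, pseudocount = 1,
                       nested = TRUE) {
  s1 <- group_mean_scores(scores, score_groups) |>
    select_susceptibility_candidates(thr_target = thr_target, thr_other = thr_other)
  stage1_genes <- s1$gene_id[s1$stage1_pass]

  expr_genes <- if (nested) intersect(tpm$gene_id, stage1_genes) else tpm$gene_id
  s2 <- if (length(expr_genes) > 0) {
    expression_enrichment(tpm[match(expr_genes, tpm$gene_id), , drop = FALSE],
                          tpm_samples, pseudocount = pseudocount) |>
      select_overexpressed(min_fold = min_fold, min_tumor_tpm = min_tumor_tpm)
  } else {
    tibble(gene_id = character(), mean_tumor_tpm = numeric(),
           mean_reference_tpm = numeric(), fold_change = numeric(),
           fold_defined = logical(), stage2_pass = logical())
  }
  stage2_genes <- intersect(s2$gene_id[s2$stage2_pass],
                            if (nested) stage1_genes else s2$gene_id)

  surv_genes <- if (nested) {
    intersect(setdiff(names(surv), c("sample_id", "time", "event")), stage2_genes)
  } else {
    setdiff(names(surv), c("sample_id", "time", "event"))
  }
  s3 <- if (length(surv_genes) > 0) {
    hazard_screen(surv, genes = surv_genes, q = q)
  } else {
    tibble(gene_id = character(), n_high = integer(), n_low = integer(),
           log_hr = numeric(), hr = numeric(), ci_lower = numeric(),
           ci_upper = numeric(), logrank_chi2 = numeric(),
           logrank_p = numeric(), converged = logical(), note = character())
  }
  if (nrow(s3) > 0) {
    s3 <- s3 |>
      mutate(stage3_rank = dplyr::dense_rank(desc(.data$hr)))
  } else {
    s3$stage3_rank <- integer()
  }

  out <- s1 |>
    left_join(select(s2, -dplyr::any_of("eligible")), by = "gene_id") |>
    left_join(s3, by = "gene_id") |>
    mutate(
      stage2_pass = !is.na(.data$stage2_pass) & .data$stage2_pass,
      candidate = .data$stage1_pass & .data$stage2_pass &
        !is.na(.data$hr) & .data$hr > hr_cut &
        !is.na(.data$logrank_p) & .data$logrank_p < p_cut
    )
  funnel <- c(universe = nrow(out),
              stage1 = sum(out$stage1_pass),
              stage2 = sum(out$stage2_pass),
              candidates = sum(out$candidate))
  structure(out,
            funnel = funnel,
            thresholds = list(thr_target = thr_target, thr_other = thr_other,
                              min_fold = min_fold, min_tumor_tpm = min_tumor_tpm,
                              q = q, hr_cut = hr_cut, p_cut = p_cut,
                              pseudocount = pseudocount, nested = nested),
            class = c("screen_result", class(out)))
}

#' @rdname run_screen
#' @param x A `screen_result`.
#' @param ... Unused.
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  f <- attr(x, "funnel")
  tibble(universe = f[["universe"]], stage1 = f[["stage1"]],
         stage2 = f[["stage2"]], candidates = f[["candidates"]])
}

#' Run the screen from files and write results with a manifest
#'
#' File-based wrapper around [run_screen()]: reads the dependency matrix,
#' group table, TPM matrix, sample table and survival table from TSV,
#' runs the screen, and writes `screen_result.tsv` plus a
#' `manifest.json` recording thresholds, input checksums and the package
#' version, so a run can be audited and reproduced bit-exactly.
#'
#' @param config Named list (or path to a YAML file with the same keys):
#'   `scores`, `groups`, `tpm`, `samples`, `surv` (input TSV paths),
#'   `out_dir`, and optionally any threshold argument of [run_screen()].
#' @return The `screen_result` tibble, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_screen_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  need <- c("scores", "groups", "tpm", "samples", "surv", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    abort(sprintf("config is missing: %s", paste(missing, collapse = ", ")))
  }
  paths <- unlist(config[c("scores", "groups", "tpm", "samples", "surv")])
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    abort(sprintf("input file(s) not found: %s", paste(absent, collapse = ", ")))
  }
  thr_args <- config[intersect(names(config),
                               c("thr_target", "thr_other", "min_fold",
                                 "min_tumor_tpm", "q", "hr_cut", "p_cut",
                                 "pseudocount", "nested"))]
  res <- do.call(run_screen, c(list(
    scores = read_matrix_tsv(config$scores),
    score_groups = readr::read_tsv(config$groups, show_col_types = FALSE),
    tpm = read_matrix_tsv(config$tpm),
    tpm_samples = readr::read_tsv(config$samples, show_col_types = FALSE),
    surv = readr::read_tsv(config$surv, show_col_types = FALSE)
  ), thr_args))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(res), file.path(config$out_dir, "screen_result.tsv"))
  manifest <- list(
    package = "susceptigene",
    version = as.character(utils::packageVersion("susceptigene")),
    thresholds = attr(res, "thresholds"),
    funnel = as.list(attr(res, "funnel")),
    inputs = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Integrative promoter-binding versus expression-change enrichment
#'
#' Builds the gene set of the `top_n` genes with the highest aggregated
#' promoter peak signal ([promoter_signal_rank()]), ranks all genes by
#' their knockout-versus-control log2 fold change, and tests the set's
#' position in that ranking with [gsea_preranked()]. A negative enrichment
#' score with small p means the strongly promoter-bound genes concentrate
#' among the downregulated genes — the signature of the bound factor acting
#' as a direct activator.
#'
#' @param peaks,promoters Interval tibbles (see [promoter_signal_rank()]).
#' @param de_results Tibble with `gene_id` and `log2_fold_change` (e.g.
#'   from [de_test()]).
#' @param top_n Promoter-signal set size (default 200).
#' @param n_perm,weight_p,seed Passed to [gsea_preranked()].
#' @param aggregate Promoter signal aggregation, `"max"` or `"sum"`.
#' @return One-row enrichment tibble (see [gsea_preranked()]).
#' @export
run_integrative <- function(peaks, promoters, de_results, top_n = 200,
                            n_perm = 1000, weight_p = 1, seed = NULL,
                            aggregate = c("max", "sum")) {
  stopifnot(all(c("gene_id", "log2_fold_change") %in% names(de_results)))
  sig <- promoter_signal_rank(peaks, promoters, top_n = top_n,
                              aggregate = match.arg(aggregate))
  ranked <- tibble(gene_id = de_results$gene_id,
                   metric = de_results$log2_fold_change)
  members <- intersect(sig$gene_id, ranked$gene_id)
  if (length(members) == 0) {
    abort("no promoter-signal gene appears in the differential-expression results")
  }
  gsea_preranked(ranked, list(promoter_top = members), n_perm = n_perm,
                 weight_p = weight_p, seed = seed)
}
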
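#' Configuration for the synthetic-data generators
#'
#' A `sim_config` bundles every knob of the seeded generators so that one
#' object fully determines all synthetic inputs (identical configs give
#' bit-identical outputs). Defaults follow the study design the package
#' emulates: 13 target-type (AML) cell lines against 345 background lines,
#' a 173-sample tumor cohort (TCGA-LAML size) with a 70-sample reference
#' group, and four replicates per RNA-seq condition. The full screen used
#' 17,670 genes; `n_genes = 2000` is the desk-scale default.
#'
#' Planted structure is declared by gene-id sets plus an effect size:
#' `essential_genes` get their target-line dependency scores shifted by
#' `essential_effect`; `overexpressed_genes` get their tumor-group TPM
#' multiplied by `overexpressed_fold`; `prognostic_genes` multiply the event
#' hazard by `prognostic_hr` for samples in their top expression quartile;
#' `de_genes` carry `de_fold` in the knockout condition. Planted
#' overexpressed genes are pinned to the population-typical expression
#' baseline (`tpm_meanlog`) before the fold is applied so that the planted
#' fold is identifiable ground truth rather than a fold on a silent gene.
#'
#' @param seed Integer seed; expanded into independent per-generator
#'   substreams, so adding one generator never perturbs the others' draws.
#' @param n_genes Number of genes in the universe.
#' @param n_target_lines,n_other_lines Cell-line counts for the dependency
#'   matrix (defaults 13 and 345).
#' @param essential_genes,essential_effect Planted target-specific essential
#'   genes and the (negative) mean score shift applied to their target lines.
#' @param overexpressed_genes,overexpressed_fold Planted tumor-overexpressed
#'   genes and the linear TPM fold multiplier.
#' @param prognostic_genes,prognostic_hr Planted prognostic genes and the
#'   true hazard ratio of their top expression quartile versus the rest.
#' @param risk_fold Expression boost of the latent high-risk sample group
#'   in the planted prognostic genes (default 4). Prognostic genes are
#'   generated as a co-expressed signature: one latent quartile of tumor
#'   samples is upregulated in all of them and carries the hazard increase
#'   once, so each gene's marginal high-versus-low hazard ratio equals
#'   `prognostic_hr` instead of compounding across genes.
#' @param noise_sd Standard deviation of dependency-score noise around 0.
#' @param tpm_meanlog,tpm_sdlog_gene,tpm_sdlog_sample Log-normal expression
#'   background: gene baselines are drawn with `meanlog = tpm_meanlog` and
#'   `sdlog = tpm_sdlog_gene`; per-sample noise has `sdlog = tpm_sdlog_sample`.
#' @param n_tumor,n_reference Expression sample counts per group.
#' @param n_samples_survival Tumor samples carried into the survival table.
#' @param censoring_rate Target fraction of censored samples in `[0, 1]`.
#' @param baseline_hazard Baseline event hazard (per month).
#' @param survival_family `"exponential"` (default) or `"weibull"` baseline.
#' @param weibull_shape Shape parameter used when `survival_family` is
#'   `"weibull"`.
#' @param nb_dispersion Negative-binomial dispersion of generated counts
#'   (variance `mu + dispersion * mu^2`); 0 means Poisson.
#' @param n_replicates Replicates per condition for the count matrix.
#' @param count_meanlog,count_sdlog Log-normal distribution of gene mean
#'   counts.
#' @param de_genes,de_fold Planted differentially expressed genes and their
#'   knockout/control fold change; `de_fold` may be a vector along
#'   `de_genes` (values below 1 plant downregulation).
#' @param n_peaks,promoter_fraction Peak count for the toy genome and the
#'   fraction of peaks placed inside promoters.
#' @param promoter_width,peak_width Interval widths in base pairs.
#' @param n_chroms Number of toy chromosomes.
#' @param chrom_length Optional per-chromosome length; by default sized so
#'   all promoters fit without overlap.
#'
#' @return An object of class `sim_config` (a validated named list with a
#'   `gene_ids` element).
#' @seealso [gen_dependency()], [gen_expression()], [gen_survival()],
#'   [gen_counts()], [gen_genome()], [planted_truth()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 100,
#'                   essential_genes = sprintf("g%05d", 1:5))
#' dep <- gen_dependency(cfg)
#' dim(dep$scores)
sim_config <- function(seed,
                       n_genes = 2000,
                       n_target_lines = 13,
                       n_other_lines = 345,
                       essential_genes = character(),
                       essential_effect = -1,
                       overexpressed_genes = character(),
                       overexpressed_fold = 8,
                       prognostic_genes = character(),
                       prognostic_hr = 2.5,
                       risk_fold = 4,
                       noise_sd = 0.15,
                       tpm_meanlog = log(10),
                       tpm_sdlog_gene = 1,
                       tpm_sdlog_sample = 0.5,
                       n_tumor = 173,
                       n_reference = 70,
                       n_samples_survival = 173,
                       censoring_rate = 0.3,
                       baseline_hazard = 0.02,
                       survival_family = c("exponential", "weibull"),
                       weibull_shape = 1.2,
                       nb_dispersion = 0.1,
                       n_replicates = 4,
                       count_meanlog = log(200),
                       count_sdlog = 1,
                       de_genes = character(),
                       de_fold = 4,
                       n_peaks = 1000,
                       promoter_fraction = 0.3,
                       promoter_width = 2000,
                       peak_width = 400,
                       n_chroms = 2,
                       chrom_length = NULL) {
  seed <- check_count(seed, "seed", min = 0L)
  cfg <- list(
    seed = seed,
    n_genes = check_count(n_genes, "n_genes"),
    n_target_lines = check_count(n_target_lines, "n_target_lines"),
    n_other_lines = check_count(n_other_lines, "n_other_lines"),
    essential_genes = as.character(essential_genes),
    essential_effect = as.numeric(essential_effect),
    overexpressed_genes = as.character(overexpressed_genes),
    overexpressed_fold = as.numeric(overexpressed_fold),
    prognostic_genes = as.character(prognostic_genes),
    prognostic_hr = as.numeric(prognostic_hr),
    risk_fold = as.numeric(risk_fold),
    noise_sd = as.numeric(noise_sd),
    tpm_meanlog = as.numeric(tpm_meanlog),
    tpm_sdlog_gene = as.numeric(tpm_sdlog_gene),
    tpm_sdlog_sample = as.numeric(tpm_sdlog_sample),
    n_tumor = check_count(n_tumor, "n_tumor"),
    n_reference = check_count(n_reference, "n_reference"),
    n_samples_survival = check_count(n_samples_survival, "n_samples_survival"),
    censoring_rate = check_fraction(censoring_rate, "censoring_rate"),
    baseline_hazard = as.numeric(baseline_hazard),
    survival_family = match.arg(survival_family),
    weibull_shape = as.numeric(weibull_shape),
    nb_dispersion = as.numeric(nb_dispersion),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    count_meanlog = as.numeric(count_meanlog),
    count_sdlog = as.numeric(count_sdlog),
    de_genes = as.character(de_genes),
    de_fold = as.numeric(de_fold),
    n_peaks = check_count(n_peaks, "n_peaks"),
    promoter_fraction = check_fraction(promoter_fraction, "promoter_fraction"),
    promoter_width = check_count(promoter_width, "promoter_width"),
    peak_width = check_count(peak_width, "peak_width"),
    n_chroms = check_count(n_chroms, "n_chroms"),
    chrom_length = if (is.null(chrom_length)) NULL else as.numeric(chrom_length)
  )
  if (cfg$noise_sd < 0) abort("'noise_sd' must be >= 0")
  if (cfg$nb_dispersion < 0) abort("'nb_dispersion' must be >= 0")
  if (cfg$baseline_hazard <= 0) abort("'baseline_hazard' must be > 0")
  if (cfg$essential_effect > 0) abort("'essential_effect' must be <= 0 (dependency depletion)")
  if (any(cfg$overexpressed_fold <= 0) || any(cfg$de_fold <= 0)) {
    abort("fold multipliers must be > 0")
  }
  if (!length(cfg$de_fold) %in% c(1L, length(cfg$de_genes)) && length(cfg$de_genes) > 0) {
    abort("'de_fold' must have length 1 or length(de_genes)")
  }
  cfg$gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  for (set in c("essential_genes", "overexpressed_genes", "prognostic_genes", "de_genes")) {
    extra <- setdiff(cfg[[set]], cfg$gene_ids)
    if (length(extra) > 0) {
      abort(sprintf("'%s' contains ids outside the gene universe: %s",
                    set, paste(head(extra, 5), collapse = ", ")))
    }
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d genes | %d target + %d other cell lines\n",
              x$seed, x$n_genes, x$n_target_lines, x$n_other_lines))
  cat(sprintf("  planted: %d essential (%.2f), %d overexpressed (x%.1f), %d prognostic (HR %.2f), %d DE\n",
              length(x$essential_genes), x$essential_effect,
              length(x$overexpressed_genes), x$overexpressed_fold,
              length(x$prognostic_genes), x$prognostic_hr,
              length(x$de_genes)))
  invisible(x)
}

#' Planted ground truth of a simulation configuration
#'
#' Collects the planted gene sets and effect sizes of a [sim_config()] in a
#' plain list, suitable for JSON serialisation as a truth sidecar next to
#' generated datasets, so downstream tests can score sensitivity and FDR
#' against known truth.
#'
#' @param cfg A [sim_config()].
#' @return A named list of planted sets and effects.
#' @export
planted_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  list(
    seed = cfg$seed,
    n_genes = cfg$n_genes,
    essential = list(genes = cfg$essential_genes, effect = cfg$essential_effect),
    overexpressed = list(genes = cfg$overexpressed_genes, fold = cfg$overexpressed_fold),
    prognostic = list(genes = cfg$prognostic_genes, hazard_ratio = cfg$prognostic_hr),
    differential = list(genes = cfg$de_genes, fold = cfg$de_fold)
  )
}

#' Write the planted-truth sidecar as JSON
#'
#' @param cfg A [sim_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(cfg, path) {
  jsonlite::write_json(planted_truth(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
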
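# Seeded generators for every input class consumed by the screen. Each
# generator draws from its own substream of cfg$seed, so outputs are
# reproducible independently of which other generators run.

#' Generate a synthetic CRISPR dependency matrix
#'
#' Background dependency scores are Normal(0, `noise_sd`), the approximate
#' behaviour of non-essential genes in genome-wide knockout screens. Planted
#' essential genes have their target-line scores shifted by
#' `essential_effect` (negative: knockout depletes the cells), leaving the
#' background lines untouched — the signature of a target-type-specific
#' susceptibility gene.
#'
#' @param cfg A [sim_config()].
#' @return A list with `scores` (tibble: `gene_id` plus one column per cell
#'   line) and `groups` (tibble: `cell_line_id`, `group` in
#'   `{"target","other"}`).
#' @export
#' @examples
#' dep <- gen_dependency(sim_config(seed = 1, n_genes = 50,
#'                                  essential_genes = c("g00001", "g00002")))
#' dep$groups
gen_dependency <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, 1L))
  n_lines <- cfg$n_target_lines + cfg$n_other_lines
  line_ids <- c(sprintf("target_%02d", seq_len(cfg$n_target_lines)),
                sprintf("other_%03d", seq_len(cfg$n_other_lines)))
  groups <- tibble(
    cell_line_id = line_ids,
    group = rep(c("target", "other"), c(cfg$n_target_lines, cfg$n_other_lines))
  )
  m <- matrix(rnorm(cfg$n_genes * n_lines, mean = 0, sd = cfg$noise_sd),
              nrow = cfg$n_genes, ncol = n_lines,
              dimnames = list(cfg$gene_ids, line_ids))
  planted <- match(cfg$essential_genes, cfg$gene_ids)
  if (length(planted) > 0) {
    m[planted, seq_len(cfg$n_target_lines)] <-
      m[planted, seq_len(cfg$n_target_lines)] + cfg$essential_effect
  }
  list(scores = matrix_to_tbl(m), groups = groups)
}

#' Generate a synthetic TPM expression matrix
#'
#' The background is log-normal: each gene draws a baseline
#' `meanlog ~ Normal(tpm_meanlog, tpm_sdlog_gene)` shared between the tumor
#' and reference groups, and each measurement adds sample-level log-normal
#' noise with `sdlog = tpm_sdlog_sample`. Planted overexpressed genes are
#' pinned to the population-typical baseline (`tpm_meanlog`) and have every
#' tumor-group value multiplied by `overexpressed_fold`, so the tumor median
#' is the reference median times the fold.
#'
#' Planted prognostic genes form a co-expressed signature: a latent
#' high-risk quartile of tumor samples is drawn once and upregulated by
#' `risk_fold` in every prognostic gene, so those genes' top expression
#' quartiles coincide (up to sample noise) and mark the same patients.
#' [gen_survival()] raises the hazard of exactly that group.
#'
#' @param cfg A [sim_config()].
#' @return A list with `tpm` (tibble: `gene_id` plus one column per sample)
#'   and `samples` (tibble: `sample_id`, `group` in `{"tumor","reference"}`).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, 2L))
  sample_ids <- c(sprintf("tumor_%03d", seq_len(cfg$n_tumor)),
                  sprintf("ref_%03d", seq_len(cfg$n_reference)))
  samples <- tibble(
    sample_id = sample_ids,
    group = rep(c("tumor", "reference"), c(cfg$n_tumor, cfg$n_reference))
  )
  n_samp <- cfg$n_tumor + cfg$n_reference
  mu <- rnorm(cfg$n_genes, cfg$tpm_meanlog, cfg$tpm_sdlog_gene)
  planted <- match(cfg$overexpressed_genes, cfg$gene_ids)
  mu[planted] <- cfg$tpm_meanlog
  noise <- matrix(rnorm(cfg$n_genes * n_samp, 0, cfg$tpm_sdlog_sample),
                  nrow = cfg$n_genes)
  m <- exp(mu + noise)
  dimnames(m) <- list(cfg$gene_ids, sample_ids)
  if (length(planted) > 0) {
    m[planted, seq_len(cfg$n_tumor)] <-
      m[planted, seq_len(cfg$n_tumor)] * cfg$overexpressed_fold
  }
  risk <- integer(0)
  prog <- match(cfg$prognostic_genes, cfg$gene_ids)
  if (length(prog) > 0) {
    n_risk <- ceiling(0.25 * cfg$n_tumor)
    risk <- sort(sample.int(cfg$n_tumor, n_risk))
    m[prog, risk] <- m[prog, risk] * cfg$risk_fold
  }
  list(tpm = matrix_to_tbl(m), samples = samples,
       risk_samples = sample_ids[risk])
}

#' Generate a synthetic survival table tied to an expression matrix
#'
#' Event times follow a proportional-hazards model over the tumor samples of
#' `expression`: the baseline is exponential with rate `baseline_hazard`
#' (Weibull with `weibull_shape` when configured), and samples in the top
#' expression quartile of a planted prognostic gene have their hazard
#' multiplied by `prognostic_hr`. The multiplier is applied once per
#' sample, not once per gene: because [gen_expression()] generates the
#' prognostic genes as a co-expressed signature, their top quartiles mark
#' the same high-risk patients, and compounding the hazard across planted
#' genes would distort every gene's marginal hazard ratio away from the
#' declared truth. Censoring is independent uniform on
#' `[0, b]`, with `b` solved so the expected censored fraction under the
#' baseline hazard matches `censoring_rate`.
#'
#' @param cfg A [sim_config()].
#' @param expression Output of [gen_expression()] (or a compatible list with
#'   `tpm` and `samples`).
#' @param genes Gene ids carried into the table as expression covariates;
#'   defaults to all genes.
#' @return A tibble with `sample_id`, `time`, `event` (1 = event observed)
#'   and one numeric column per covariate gene.
#' @export
gen_survival <- function(cfg, expression, genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, 3L))
  tumor_ids <- expression$samples$sample_id[expression$samples$group == "tumor"]
  if (length(tumor_ids) < cfg$n_samples_survival) {
    abort(sprintf("expression has %d tumor samples; %d required",
                  length(tumor_ids), cfg$n_samples_survival))
  }
  ids <- tumor_ids[seq_len(cfg$n_samples_survival)]
  tpm <- tbl_to_matrix(expression$tpm)
  missing <- setdiff(cfg$prognostic_genes, rownames(tpm))
  if (length(missing) > 0) {
    abort(sprintf("planted prognostic gene(s) absent from expression: %s",
                  paste(missing, collapse = ", ")))
  }
  if (is.null(genes)) genes <- rownames(tpm)
  stopifnot(all(genes %in% rownames(tpm)))

  if (!is.null(expression$risk_samples)) {
    boosted <- ids %in% expression$risk_samples
  } else {
    # expression from an external source: fall back to the per-gene top
    # quartiles (their union, so the multiplier still applies only once)
    boosted <- rep(FALSE, length(ids))
    for (g in cfg$prognostic_genes) {
      x <- tpm[g, ids]
      boosted <- boosted | x >= quantile(x, 0.75)
    }
  }
  rate <- cfg$baseline_hazard * ifelse(boosted, cfg$prognostic_hr, 1)
  time_event <- if (cfg$survival_family == "exponential") {
    rexp(length(ids), rate = rate)
  } else {
    # Weibull with per-sample scale so the hazard multiplier acts
    # proportionally: h(t) = rate * shape * t^(shape-1).
    (rexp(length(ids), rate = rate))^(1 / cfg$weibull_shape)
  }
  if (cfg$censoring_rate > 0) {
    b <- censor_horizon(cfg$baseline_hazard, cfg$censoring_rate)
    cens <- runif(length(ids), 0, b)
    event <- as.integer(time_event <= cens)
    obs <- pmin(time_event, cens)
  } else {
    event <- rep(1L, length(ids))
    obs <- time_event
  }
  covar <- t(tpm[genes, ids, drop = FALSE])
  bind_cols(tibble(sample_id = ids, time = obs, event = event),
            as_tibble(covar, .name_repair = "minimal"))
}

# Horizon b of Uniform(0, b) censoring such that P(censored) = rate for
# exponential event times with hazard lambda:
# P(C < T) = E[exp(-lambda C)] = (1 - exp(-lambda b)) / (lambda b).
censor_horizon <- function(lambda, rate) {
  stopifnot(rate > 0, rate < 1)
  f <- function(b) (1 - exp(-lambda * b)) / (lambda * b) - rate
  uniroot(f, lower = 1e-8 / lambda, upper = 1e8 / lambda, tol = 1e-10)$root
}

#' Generate a synthetic knockout-versus-control count matrix
#'
#' Integer counts are negative-binomial with per-gene log-normal mean and
#' dispersion `nb_dispersion` (variance `mu + dispersion * mu^2`;
#' dispersion 0 means Poisson). Planted differential genes have their
#' knockout-condition mean multiplied by `de_fold`. With `noise = FALSE`
#' counts equal the rounded means exactly, a degenerate limit useful for
#' closed-form checks.
#'
#' @param cfg A [sim_config()].
#' @param noise Draw sampling noise? Default `TRUE`.
#' @return A list with `counts` (tibble: `gene_id` plus one column per
#'   sample) and `conditions` (tibble: `sample_id`, `condition` in
#'   `{"control","knockout"}`).
#' @export
gen_counts <- function(cfg, noise = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, 4L))
  n_rep <- cfg$n_replicates
  sample_ids <- c(sprintf("ctrl_%d", seq_len(n_rep)), sprintf("ko_%d", seq_len(n_rep)))
  conditions <- tibble(sample_id = sample_ids,
                       condition = rep(c("control", "knockout"), each = n_rep))
  base_mu <- rlnorm(cfg$n_genes, cfg$count_meanlog, cfg$count_sdlog)
  fold <- rep(1, cfg$n_genes)
  if (length(cfg$de_genes) > 0) {
    fold[match(cfg$de_genes, cfg$gene_ids)] <- rep(cfg$de_fold, length.out = length(cfg$de_genes))
  }
  mu <- cbind(matrix(base_mu, cfg$n_genes, n_rep),
              matrix(base_mu * fold, cfg$n_genes, n_rep))
  if (!noise) {
    base_int <- pmax(1, round(base_mu))
    m <- cbind(matrix(base_int, cfg$n_genes, n_rep),
               matrix(round(base_int * fold), cfg$n_genes, n_rep))
  } else if (cfg$nb_dispersion == 0) {
    m <- matrix(rpois(length(mu), lambda = mu), nrow = cfg$n_genes)
  } else {
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                nrow = cfg$n_genes)
  }
  dimnames(m) <- list(cfg$gene_ids, sample_ids)
  list(counts = matrix_to_tbl(m), conditions = conditions)
}
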
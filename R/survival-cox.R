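# Univariate Cox proportional-hazards regression by Newton-Raphson on the
# partial likelihood, with Breslow (default) or Efron handling of tied
# event times, plus the per-gene hazard screen built on top of it.

# Core fitter on raw vectors. Returns beta, information at the final beta,
# iteration count and a convergence flag. Monotone likelihood (separation)
# is flagged, not thrown.
cox_fit_core <- function(t, d, x, ties = "breslow", tol = 1e-8, max_iter = 50L) {
  ord <- order(t, decreasing = TRUE)
  t <- t[ord]; d <- d[ord]; x <- x[ord]
  grp <- cumsum(!duplicated(t))                # distinct times, descending
  last_idx <- cumsum(rle(grp)$lengths)
  dsum <- unname(rowsum(d, grp)[, 1])
  ev_grp <- which(dsum > 0)
  sx_all <- unname(rowsum(d * x, grp)[, 1])
  beta <- 0; info <- NA_real_; converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- exp(beta * x); wx <- w * x; wxx <- wx * x
    c0 <- cumsum(w)[last_idx]
    c1 <- cumsum(wx)[last_idx]
    c2 <- cumsum(wxx)[last_idx]
    if (ties == "breslow") {
      S0 <- c0[ev_grp]; r1 <- c1[ev_grp] / S0
      U <- sum(sx_all[ev_grp] - dsum[ev_grp] * r1)
      info <- sum(dsum[ev_grp] * (c2[ev_grp] / S0 - r1^2))
    } else {
      s0 <- unname(rowsum(d * w, grp)[, 1])
      s1 <- unname(rowsum(d * wx, grp)[, 1])
      s2 <- unname(rowsum(d * wxx, grp)[, 1])
      U <- 0; info <- 0
      for (g in ev_grp) {
        du <- dsum[g]; k <- (seq_len(du) - 1) / du
        den <- c0[g] - k * s0[g]
        n1 <- c1[g] - k * s1[g]
        n2 <- c2[g] - k * s2[g]
        U <- U + sx_all[g] - sum(n1 / den)
        info <- info + sum(n2 / den - (n1 / den)^2)
      }
    }
    if (!is.finite(U) || !is.finite(info) || info <= 0) {
      converged <- FALSE
      break
    }
    step <- U / info
    beta <- beta + step
    if (abs(beta) > 15) {                      # monotone likelihood
      converged <- FALSE
      break
    }
    if (abs(step) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, info = info, iterations = iter, converged = converged)
}

#' Univariate Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood for a single covariate by
#' Newton-Raphson (convergence when the update falls below `tol`, at most
#' `max_iter` iterations), with Breslow handling of tied event times by
#' default (Efron optional). The 95% confidence interval comes from the
#' observed information at the maximum. A monotone likelihood (complete
#' separation, e.g. all events in one group) is returned as a flagged,
#' non-converged result with infinite interval bounds rather than an error.
#'
#' @param data Data frame with time, event and covariate columns.
#' @param x Column (tidy-eval) holding the covariate; for a high/low
#'   contrast use a 0/1 indicator (1 = high), so `hr > 1` means higher
#'   hazard in the high group.
#' @param time,event Columns (tidy-eval); defaults `time` and `event`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol,max_iter Newton-Raphson controls.
#' @return An object of class `cox_hr`: `log_hr`, `se`, `hr`, `ci_lower`,
#'   `ci_upper` (95%), Wald `statistic` and `p_value`, `n`, `n_event`,
#'   `iterations`, `converged`.
#' @export
#' @examples
#' d <- tibble::tibble(time = c(2, 4, 6, 8, 10, 12), event = 1,
#'                     high = c(1, 1, 1, 0, 0, 0))
#' tidy(cox_hr(d, high))
cox_hr <- function(data, x, time = time, event = event,
                   ties = c("breslow", "efron"), tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  t <- dplyr::pull(data, {{ time }})
  d <- dplyr::pull(data, {{ event }})
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  if (any(t <= 0) || anyNA(t)) abort("times must be positive and non-missing")
  if (!all(d %in% c(0, 1))) abort("event indicator must be 0/1")
  if (anyNA(xv)) abort("missing covariate values")
  if (sum(d) < 1) abort("at least one event is required")
  if (stats::var(xv) == 0) abort("covariate is constant; hazard ratio undefined")
  fit <- cox_fit_core(t, d, xv, ties = ties, tol = tol, max_iter = max_iter)
  se <- if (fit$converged && is.finite(fit$info) && fit$info > 0) {
    1 / sqrt(fit$info)
  } else {
    Inf
  }
  z <- qnorm(0.975)
  structure(list(
    log_hr = fit$beta,
    se = se,
    hr = exp(fit$beta),
    ci_lower = exp(fit$beta - z * se),
    ci_upper = exp(fit$beta + z * se),
    statistic = fit$beta / se,
    p_value = if (is.finite(se)) 2 * stats::pnorm(-abs(fit$beta / se)) else NA_real_,
    n = length(t),
    n_event = sum(d),
    iterations = fit$iterations,
    converged = fit$converged,
    ties = ties
  ), class = "cox_hr")
}

#' @export
print.cox_hr <- function(x, ...) {
  cat(sprintf("Cox PH (%s ties): HR = %.4g [%.4g, %.4g], log HR = %.4g (se %.3g)\n",
              x$ties, x$hr, x$ci_lower, x$ci_upper, x$log_hr, x$se))
  cat(sprintf("  n = %d, events = %d, %d iterations%s\n", x$n, x$n_event,
              x$iterations, if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' @rdname cox_hr
#' @param ... Unused.
#' @method tidy cox_hr
#' @export
tidy.cox_hr <- function(x, ...) {
  tibble(term = "x", estimate = x$log_hr, std.error = x$se,
         statistic = x$statistic, p.value = x$p_value,
         hr = x$hr, conf.low = x$ci_lower, conf.high = x$ci_upper)
}

#' @rdname cox_hr
#' @method glance cox_hr
#' @export
glance.cox_hr <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event, iterations = x$iterations,
         converged = x$converged, ties = x$ties)
}

#' Per-gene hazard screen over quantile-stratified expression
#'
#' For each gene, samples are split into top and bottom expression
#' quantiles ([stratify_by_quantile()]); the high-versus-low contrast is
#' then scored by a univariate Cox model ([cox_hr()], indicator 1 = high)
#' and a log-rank test ([logrank_test()]). Genes whose expression is
#' constant, or whose fit fails, are flagged in the `note` column and the
#' screen continues. The result is sortable by `hr`, reproducing the
#' hazard-ratio ranking of the screen's third stage.
#'
#' @param surv Survival tibble: `sample_id`, `time`, `event`, plus one
#'   numeric column per gene.
#' @param genes Gene columns to screen; defaults to every column after
#'   `sample_id`, `time`, `event`.
#' @param q Quantile fraction for stratification (default 0.25).
#' @param ties,inclusive Passed to [cox_hr()] / [stratify_by_quantile()].
#' @return A tibble with one row per gene: `gene_id`, `n_high`, `n_low`,
#'   `log_hr`, `hr`, `ci_lower`, `ci_upper`, `logrank_chi2`, `logrank_p`,
#'   `converged`, `note`.
#' @export
hazard_screen <- function(surv, genes = NULL, q = 0.25,
                          ties = c("breslow", "efron"), inclusive = TRUE) {
  ties <- match.arg(ties)
  reserved <- c("sample_id", "time", "event")
  stopifnot(all(reserved %in% names(surv)))
  if (is.null(genes)) genes <- setdiff(names(surv), reserved)
  missing <- setdiff(genes, names(surv))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) absent from survival table: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  rows <- map(genes, function(g) {
    x <- surv[[g]]
    blank <- tibble(gene_id = g, n_high = NA_integer_, n_low = NA_integer_,
                    log_hr = NA_real_, hr = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    logrank_chi2 = NA_real_, logrank_p = NA_real_,
                    converged = NA, note = NA_character_)
    if (anyNA(x) || diff(range(x)) == 0) {
      blank$note <- "constant_or_missing_expression"
      return(blank)
    }
    res <- tryCatch({
      strat <- stratify_by_quantile(surv, g, q = q, inclusive = inclusive)
      sub <- strat |> filter(.data$strat_group != "mid")
      sub$high <- as.integer(sub$strat_group == "high")
      fit <- cox_hr(sub, high, ties = ties)
      lr <- logrank_test(sub, strat_group)
      tibble(gene_id = g,
             n_high = sum(sub$high == 1L), n_low = sum(sub$high == 0L),
             log_hr = fit$log_hr, hr = fit$hr,
             ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
             logrank_chi2 = lr$statistic, logrank_p = lr$p_value,
             converged = fit$converged,
             note = if (fit$converged) NA_character_ else "not_converged")
    }, error = function(e) {
      blank$note <- conditionMessage(e)
      blank
    })
    res
  })
  bind_rows(rows)
}
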
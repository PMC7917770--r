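# Stage 3 building blocks implemented from first principles: quantile
# stratification, the Kaplan-Meier product-limit estimator and the
# two-group log-rank test.

#' Stratify samples by expression quantile
#'
#' Splits samples into a `low` group (value at or below the `q`-th
#' quantile) and a `high` group (value at or above the `(1-q)`-th
#' quantile); samples strictly between the cuts are labelled `mid` and
#' excluded from survival comparisons. `q = 0.25` reproduces a
#' top-versus-bottom quartile contrast; `q = 0.5` is a median split
#' covering all samples. Samples exactly at a cut go to the extreme group
#' (inclusive cuts) for determinism; set `inclusive = FALSE` for strict
#' cuts.
#'
#' @param data Data frame with one row per sample.
#' @param value Column (tidy-eval) holding the per-sample expression value.
#' @param q Quantile fraction in `(0, 0.5]` (default 0.25).
#' @param inclusive Assign samples exactly at a cut to the extreme group
#'   (default `TRUE`).
#' @return `data` with an added `strat_group` factor (`low`/`mid`/`high`).
#' @export
#' @examples
#' d <- tibble::tibble(sample_id = letters[1:8], expr = 1:8)
#' stratify_by_quantile(d, expr, q = 0.25)
stratify_by_quantile <- function(data, value, q = 0.25, inclusive = TRUE) {
  if (q <= 0 || q > 0.5) abort("'q' must lie in (0, 0.5]")
  x <- dplyr::pull(data, {{ value }})
  if (length(x) < 4) abort("need at least 4 samples to stratify")
  if (anyNA(x)) abort("missing expression values")
  if (diff(range(x)) == 0) abort("all expression values identical; no stratification possible")
  lo_cut <- quantile(x, q, names = FALSE)
  hi_cut <- quantile(x, 1 - q, names = FALSE)
  if (inclusive) {
    grp <- ifelse(x <= lo_cut, "low", ifelse(x >= hi_cut, "high", "mid"))
  } else {
    grp <- ifelse(x < lo_cut, "low", ifelse(x > hi_cut, "high", "mid"))
  }
  if (!any(grp == "low") || !any(grp == "high")) {
    abort("degenerate stratification: an extreme group is empty")
  }
  data |> mutate(strat_group = factor(grp, levels = c("low", "mid", "high")))
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the nonparametric survival-function estimate
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, where `d_i`
#' events occur at `t_i` among `n_i` samples still at risk. Censored times
#' reduce the risk set only. With no censoring the curve equals the
#' empirical survival function.
#'
#' @param data Data frame with `time` (positive) and `event` (0/1) columns.
#' @param time,event Columns (tidy-eval) holding follow-up time and the
#'   event indicator; defaults `time` and `event`.
#' @return A tibble of class `km_curve`, one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
#' @examples
#' km_estimate(tibble::tibble(time = 1:3, event = 1))
km_estimate <- function(data, time = time, event = event) {
  t <- dplyr::pull(data, {{ time }})
  d <- dplyr::pull(data, {{ event }})
  if (length(t) == 0) abort("empty survival input")
  if (length(t) != length(d)) abort("time and event lengths differ")
  if (any(t <= 0) || anyNA(t)) abort("times must be positive and non-missing")
  if (!all(d %in% c(0, 1))) abort("event indicator must be 0/1")
  ut <- sort(unique(t))
  n_risk <- vapply(ut, function(u) sum(t >= u), numeric(1))
  n_event <- vapply(ut, function(u) sum(t == u & d == 1), numeric(1))
  n_censor <- vapply(ut, function(u) sum(t == u & d == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    tibble(time = ut, n_risk = n_risk, n_event = n_event,
           n_censor = n_censor, survival = surv),
    class = c("km_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in group A is
#' compared with its hypergeometric expectation given the pooled risk set;
#' the squared sum of differences over the summed hypergeometric variances
#' is referred to a chi-square distribution with 1 df.
#'
#' @param data Data frame with time, event and a two-level group column.
#' @param group Column (tidy-eval) with exactly two distinct levels.
#' @param time,event Columns (tidy-eval); defaults `time` and `event`.
#' @return A list of class `logrank_test`: `statistic` (chi-square),
#'   `p_value`, `observed` and `expected` per group, `n` per group.
#' @export
logrank_test <- function(data, group, time = time, event = event) {
  t <- dplyr::pull(data, {{ time }})
  d <- dplyr::pull(data, {{ event }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("log-rank test needs exactly two groups")
  if (!all(d %in% c(0, 1))) abort("event indicator must be 0/1")
  if (sum(d) == 0) abort("no events in either group; log-rank test undefined")
  is_a <- g == lev[1]
  ev_times <- sort(unique(t[d == 1]))
  o_minus_e <- 0; v <- 0; obs_a <- 0; exp_a <- 0
  for (u in ev_times) {
    at_risk <- t >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & is_a)
    dt <- sum(t == u & d == 1)
    d1 <- sum(t == u & d == 1 & is_a)
    e1 <- dt * n1 / n
    obs_a <- obs_a + d1
    exp_a <- exp_a + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) {
      v <- v + dt * (n1 / n) * (1 - n1 / n) * (n - dt) / (n - 1)
    }
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  total_ev <- sum(d)
  structure(list(
    statistic = chi2,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
    groups = lev,
    n = c(sum(is_a), sum(!is_a)),
    observed = c(obs_a, total_ev - obs_a),
    expected = c(exp_a, total_ev - exp_a)
  ), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  %s: n = %d, observed %d, expected %.2f\n",
              x$groups, x$n, x$observed, x$expected), sep = "")
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, df = 1)
}
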
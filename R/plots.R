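# ggplot2 displays for the main result types: the dual-threshold
# dependency scatter, Kaplan-Meier step curves and the GSEA mountain plot.

#' Dependency scatter with the dual-threshold selection region
#'
#' Plots each gene's target-group average score against its background
#' average, colouring the genes selected at the given thresholds.
#'
#' @param means Output of [group_mean_scores()] (or
#'   [select_susceptibility_candidates()]).
#' @param thr_target,thr_other Thresholds drawn as dashed lines (defaults
#'   -0.5 / -0.2).
#' @return A ggplot object.
#' @export
plot_dependency_scatter <- function(means, thr_target = -0.5, thr_other = -0.2) {
  if (!"stage1_pass" %in% names(means)) {
    means <- select_susceptibility_candidates(means, thr_target, thr_other)
  }
  ggplot2::ggplot(means, ggplot2::aes(x = .data$mean_target, y = .data$mean_other,
                                      colour = .data$stage1_pass)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = thr_target, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thr_other, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red"),
                                 name = "selected") +
    ggplot2::labs(x = "average dependency score, target lines",
                  y = "average dependency score, other lines") +
    ggplot2::theme_minimal()
}

#' @rdname km_estimate
#' @param object A `km_curve`.
#' @param ... Unused.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, survival = 1),
                  as_tibble(object)[, c("time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a grouped survival table
#'
#' Estimates one [km_estimate()] curve per group and overlays them — the
#' usual high-versus-low expression display, with the log-rank p-value in
#' the subtitle.
#'
#' @param data Data frame with `time`, `event` and a group column.
#' @param group Column (tidy-eval) defining the curves.
#' @return A ggplot object.
#' @export
plot_km_groups <- function(data, group) {
  g <- as.character(dplyr::pull(data, {{ group }}))
  curves <- bind_rows(lapply(sort(unique(g)), function(lev) {
    km <- km_estimate(data[g == lev, , drop = FALSE])
    bind_rows(tibble(time = 0, survival = 1), as_tibble(km)[, c("time", "survival")]) |>
      mutate(group = lev)
  }))
  subtitle <- if (length(unique(g)) == 2 && sum(dplyr::pull(data, event)) > 0) {
    lr <- logrank_test(data, {{ group }})
    sprintf("log-rank p = %.3g", lr$p_value)
  } else {
    NULL
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' @rdname enrichment_score
#' @param object An `enrichment_score`.
#' @param ... Unused.
#' @method autoplot enrichment_score
#' @export
autoplot.enrichment_score <- function(object, ...) {
  rs <- object$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_rug(data = rs[rs$hit, , drop = FALSE], sides = "b",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank in ordered list", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f", object$es)) +
    ggplot2::theme_minimal()
}
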
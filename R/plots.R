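#' Figures
#'
#' ggplot2 views of the standard outputs: evolutionary-time curves,
#' trial-time curves (absolute or centered on the first block
#' observation), and goal-prior heatmaps (timestep x sensory state,
#' one facet per condition).
#'
#' @name plots
NULL

#' Plot evolutionary-time averages
#'
#' @param agg result of [evolutionary_aggregate()].
#' @param var which variable to draw (a value column name, e.g.
#'   `"fitness"`).
#' @return a ggplot object: mean line with a standard-error ribbon.
#' @export
plot_evolution <- function(agg, var = "fitness") {
  df <- agg$by_generation
  m <- rlang::sym(paste0("mean_", var))
  s <- rlang::sym(paste0("se_", var))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = !!m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = !!m - !!s,
                                      ymax = !!m + !!s), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = var) +
    ggplot2::theme_minimal()
}

#' Plot trial-time averages
#'
#' @param df tibble with a time column and a value column.
#' @param time `"t"` or `"rel_t"`.
#' @param var value column name (`"phi"` or `"surprisal"`).
#' @param group optional grouping column for separate lines.
#' @return a ggplot object of per-timestep means with SE ribbons.
#' @export
plot_trial_time <- function(df, var = "surprisal", time = "t",
                            group = NULL) {
  tv <- rlang::sym(time); vv <- rlang::sym(var)
  gs <- if (!is.null(group)) rlang::syms(group) else list()
  sm <- df |>
    dplyr::group_by(!!tv, !!!gs) |>
    dplyr::summarise(m = mean(!!vv), se = sd(!!vv) / sqrt(dplyr::n()),
                     .groups = "drop")
  p <- ggplot2::ggplot(sm, ggplot2::aes(x = !!tv, y = .data$m))
  if (!is.null(group))
    p <- ggplot2::ggplot(sm, ggplot2::aes(
      x = !!tv, y = .data$m, colour = .data[[group]],
      fill = .data[[group]]))
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    (if (time == "rel_t")
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed")) +
    ggplot2::labs(x = if (time == "rel_t")
      "timestep relative to first block observation" else "trial timestep",
      y = var) +
    ggplot2::theme_minimal()
}

#' Plot goal priors as heatmaps
#'
#' One tile per (timestep, sensory state), probability as fill, faceted
#' by trial type x direction (and source when several are present).
#'
#' @param priors a `goal_prior` tibble from [build_goal_priors()].
#' @return a ggplot object.
#' @export
plot_goal_priors <- function(priors) {
  multi <- length(unique(priors$source_id)) > 1L
  ggplot2::ggplot(priors, ggplot2::aes(
    x = .data$t, y = factor(.data$state, levels = rev(SENSOR_STATES)),
    fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.25, low = "grey20",
                                  mid = "white", high = "darkorange") +
    (if (multi)
      ggplot2::facet_grid(source_id ~ trial_type + direction)
     else ggplot2::facet_grid(~ trial_type + direction)) +
    ggplot2::labs(x = "trial timestep", y = "sensory state",
                  fill = "P(o)") +
    ggplot2::theme_minimal()
}
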
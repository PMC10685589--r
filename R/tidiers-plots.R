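# broom-style accessors and ggplot2 views of the result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a replicated experiment
#'
#' One row per run, system and outcome group with the recommendation rate
#' and, for the healthy group, the calibration target and the achieved
#' out-of-bag false-positive rate.
#'
#' @param x A `ctg_replication`.
#' @param ... Unused.
#' @export
tidy.ctg_replication <- function(x, ...) {
  select(
    x$runs, "run", "system", "group", "n", "n_recommended",
    "rate", "target_fp", "achieved_fp"
  )
}

#' Glance at a replicated experiment
#'
#' @param x A `ctg_replication`.
#' @param ... Unused.
#' @export
glance.ctg_replication <- function(x, ...) {
  tibble(
    n_runs = x$n_runs,
    n_failed = nrow(x$failed_runs),
    n_trees = x$n_trees,
    n_systems = length(x$systems),
    base_seed = x$base_seed
  )
}

#' @rdname tidy.ctg_replication
#' @export
tidy.ctg_calibration <- function(x, ...) {
  tibble(
    t_pat = x$t_pat,
    achieved_fp_rate = x$achieved_fp_rate,
    target_fp_rate = x$target_fp_rate,
    n_healthy = x$n_healthy
  )
}

#' @rdname tidy.ctg_replication
#' @export
glance.ctg_forest <- function(x, ...) {
  tibble(
    tag = x$tag,
    n_trees = x$n_trees,
    n_epochs = x$n_epochs,
    n_individuals = x$n_individuals,
    n_features = length(x$active_cols),
    include_parity = x$include_parity
  )
}

#' Plot recommendation rates against time before delivery
#'
#' Step curves of the fraction of each group recommended at or before each
#' time, the synthetic analogue of the usual recommendation-progression
#' figure.
#'
#' @param object A [time_course()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ctg_timecourse <- function(object, ...) {
  has_system <- "system" %in% names(object)
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$time_min, y = .data$rate,
      colour = if (has_system) .data$system else .data$group
    )
  ) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "Time before delivery (min)",
      y = "Recommendation rate",
      colour = if (has_system) "System" else "Group"
    ) +
    ggplot2::theme_minimal()
  if (has_system) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  p
}

#' @rdname autoplot.ctg_timecourse
#' @param object A `ctg_replication`.
#' @export
autoplot.ctg_replication <- function(object, ...) {
  ggplot2::ggplot(
    object$runs,
    ggplot2::aes(x = .data$system, y = .data$rate, fill = .data$system)
  ) +
    ggplot2::geom_boxplot(notch = FALSE, alpha = 0.6, outlier.size = 0.6) +
    ggplot2::geom_pointrange(
      data = object$summary,
      ggplot2::aes(
        x = .data$system, y = .data$median,
        ymin = .data$ci_low, ymax = .data$ci_high
      ),
      inherit.aes = FALSE, linewidth = 0.9, size = 0.3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "Recommendation rate",
      title = "Replicated recommendation rates (median with notch CI)"
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ctg_timecourse
#' @param recommendations,births See [time_course()].
#' @export
plot_time_course <- function(recommendations, births, ...) {
  autoplot(time_course(recommendations, births), ...)
}
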
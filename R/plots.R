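#' Plot cohort baseline log hazards
#'
#' Heatmap of posterior-mean baseline log hazards: one row per cohort cell,
#' one column per time interval. The dominant pattern in fitted models is
#' the time gradient — hazards are highest in the first week after
#' discharge.
#'
#' @param table A [cohort_baseline_table()] tibble (or a [quilt_fit()],
#'   which is summarized first).
#' @param ... Passed to [cohort_baseline_table()] when a fit is given.
#' @return A ggplot object.
#' @export
plot_cohort_hazards <- function(table, ...) {
  if (inherits(table, "quilt_fit")) table <- cohort_baseline_table(table, ...)
  ggplot2::ggplot(
    table,
    ggplot2::aes(
      x = factor(.data$interval, levels = unique(.data$interval)),
      y = factor(.data$cohort), fill = .data$mean
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b", mid = "white") +
    ggplot2::labs(
      x = "days after discharge", y = "cohort (multi-index)",
      fill = "mean log hazard",
      title = "Baseline log hazard by cohort and interval"
    ) +
    ggplot2::theme_minimal()
}

#' Plot ranked risk factors
#'
#' Point-interval display of the top predictors by absolute posterior-mean
#' log hazard ratio in one interval.
#'
#' @param table A [risk_factor_table()] tibble (or a [quilt_fit()]).
#' @param ... Passed to [risk_factor_table()] when a fit is given.
#' @return A ggplot object.
#' @export
plot_risk_factors <- function(table, ...) {
  if (inherits(table, "quilt_fit")) table <- risk_factor_table(table, ...)
  table$term <- stats::reorder(table$term, abs(table$mean))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper)) +
    ggplot2::labs(
      x = "log hazard ratio", y = NULL,
      title = sprintf("Leading risk factors, interval %s", table$interval[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot cohort-wise placement effects
#'
#' Posterior mean (and sd) of each placement indicator's log-hazard effect
#' per cohort; all means are non-positive by construction.
#'
#' @param table A [treatment_effect_table()] tibble (or a [quilt_fit()]).
#' @param interval Interval label to display (default: first available).
#' @param ... Passed to [treatment_effect_table()] when a fit is given.
#' @return A ggplot object.
#' @export
plot_treatment_effects <- function(table, interval = NULL, ...) {
  if (inherits(table, "quilt_fit")) table <- treatment_effect_table(table, ...)
  interval <- interval %||% table$interval[1]
  tab <- table[table$interval == interval, ]
  ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data$placement, y = factor(.data$cohort), fill = .data$mean)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "white") +
    ggplot2::labs(
      x = "placement (at least acuity k)", y = "cohort (multi-index)",
      fill = "mean effect",
      title = sprintf("Placement effects on log hazard, interval %s", interval)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the training trace of a variational fit
#' @param fit A [quilt_fit()].
#' @return A ggplot object of epoch-mean loss over epochs.
#' @export
plot_training_trace <- function(fit) {
  ggplot2::ggplot(fit$trace, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "epoch", y = "mean batch loss (-ELBO)",
      title = "Variational training trace"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot method for quilt fits
#' @param object A [quilt_fit()].
#' @param type One of "cohorts", "risk_factors", "treatment", "trace".
#' @param ... Passed to the underlying table builder.
#' @return A ggplot object.
#' @method autoplot quilt_fit
#' @export
autoplot.quilt_fit <- function(object, type = c("cohorts", "risk_factors", "treatment", "trace"), ...) {
  type <- match.arg(type)
  switch(type,
    cohorts = plot_cohort_hazards(object, ...),
    risk_factors = plot_risk_factors(object, ...),
    treatment = plot_treatment_effects(object, ...),
    trace = plot_training_trace(object)
  )
}
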
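#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form with half credit for ties: the probability that a
#' random positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcome labels (both classes present).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  check_two_class(labels)
  pos <- labels == 1
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: episodes sorted by decreasing score; the
#' precision at each positive is averaged over the positives.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  check_two_class(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

check_two_class <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop_input("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    stop_input("metrics undefined: labels contain a single class")
  }
  invisible(labels)
}

#' Horizon classification metrics
#'
#' AUROC and AUPRC of predicted horizon event risks against observed
#' horizon outcomes. The binary label is `1{event observed and T <=
#' horizon}`; episodes censored before the horizon have unknown status and
#' are excluded (reported in the output).
#'
#' @param data Data frame with risk scores and outcome columns.
#' @param risk,time,event Column names.
#' @param horizons Numeric horizons in days (default 30 and 90).
#' @return A tibble: horizon, n_used, n_excluded, prevalence, auroc, auprc.
#' @export
horizon_metrics <- function(data, risk = "risk", time = "time",
                            event = "event", horizons = c(30, 90)) {
  data <- as.data.frame(data)
  purrr::map_dfr(horizons, function(h) {
    known <- data[[event]] == 1 | data[[time]] >= h
    lab <- as.numeric(data[[event]][known] == 1 & data[[time]][known] <= h)
    sc <- data[[risk]][known]
    tibble::tibble(
      horizon = h, n_used = sum(known), n_excluded = sum(!known),
      prevalence = mean(lab),
      auroc = auroc(sc, lab), auprc = auprc(sc, lab)
    )
  })
}

#' Ranked time-dependent risk factors
#'
#' The top-k predictors by absolute posterior-mean log hazard ratio within
#' one time interval — the readable core of the model: every row is a
#' named threshold inequality with its additive log hazard ratio and 95%
#' interval.
#'
#' @param fit A [quilt_fit()].
#' @param interval 1-based interval index (default 1: the first week).
#' @param cells Cohort cell ids to average the materialized coefficients
#'   over (default: all cells).
#' @param top_k Rows to keep (default 40); truncated with a warning if it
#'   exceeds the coefficient count.
#' @param n_draws,seed Posterior draw settings.
#' @return A tibble sorted by `abs(mean)`: term, interval, mean, sd,
#'   lower, upper.
#' @export
risk_factor_table <- function(fit, interval = 1L, cells = NULL, top_k = 40L,
                              n_draws = 200L, seed = 1L) {
  model <- fit$model
  p <- model$p
  if (interval < 1L || interval > model$n_intervals) {
    stop_input("interval must be in 1..%d", model$n_intervals)
  }
  cells <- cells %||% seq_len(n_cells(model$lattice))
  draws <- posterior_draw_arrays(fit, n_draws, seed)
  cols <- ((interval - 1L) * p + 1L):(interval * p)
  mat <- vapply(
    draws,
    function(d) colMeans(d$B[cells, cols, drop = FALSE]),
    numeric(p)
  )
  if (p == 1L) mat <- matrix(mat, 1L)
  out <- tibble::tibble(
    term = model$features,
    interval = interval_labels(model$pem)[interval],
    mean = rowMeans(mat),
    sd = apply(mat, 1, stats::sd),
    lower = apply(mat, 1, stats::quantile, probs = 0.025),
    upper = apply(mat, 1, stats::quantile, probs = 0.975)
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$mean)))
  if (top_k > nrow(out)) {
    warning(sprintf("top_k = %d exceeds %d coefficients; returning all", top_k, nrow(out)))
    top_k <- nrow(out)
  }
  dplyr::slice_head(out, n = as.integer(top_k))
}

#' Cohort baseline log hazards
#'
#' Materialized baseline log hazard `alpha` for every cohort cell and time
#' interval: posterior mean, sd, and central 95% interval.
#'
#' @param fit A [quilt_fit()].
#' @param n_draws,seed Posterior draw settings.
#' @return A tibble: cell, cohort (multi-index label), interval, mean, sd,
#'   lower, upper. One row per cell x interval.
#' @export
cohort_baseline_table <- function(fit, n_draws = 200L, seed = 1L) {
  ps <- posterior_summary(fit, n_draws, seed)
  dplyr::select(
    dplyr::filter(ps, .data$block == "baseline"),
    "cell", "cohort", "interval", "mean", "sd", "lower", "upper"
  )
}

#' Cohort-wise placement effects
#'
#' Posterior mean and sd of each placement indicator's effect on the log
#' hazard (the local average treatment effect of stepping up to at least
#' acuity k), per cohort and interval. The non-positivity constraint
#' guarantees every mean is <= 0.
#'
#' @param fit A [quilt_fit()].
#' @param n_draws,seed Posterior draw settings.
#' @return A tibble: cell, cohort, interval, placement (`I>=k`), mean, sd,
#'   lower, upper.
#' @export
treatment_effect_table <- function(fit, n_draws = 200L, seed = 1L) {
  ps <- posterior_summary(fit, n_draws, seed)
  out <- dplyr::filter(ps, .data$block == "placement_effect")
  out <- dplyr::rename(out, placement = "term")
  dplyr::select(
    out, "cell", "cohort", "interval", "placement",
    "mean", "sd", "lower", "upper"
  )
}
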
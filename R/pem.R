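#' Piecewise exponential model (PEM) time grid
#'
#' Breakpoints partition follow-up time (days after discharge) into
#' half-open intervals `[0, b1), [b1, b2), ..., [bk, Inf)`; the hazard is
#' constant within each interval. The defaults place breaks at 1, 4 and 9
#' weeks, giving four intervals.
#'
#' @param breakpoints Strictly increasing positive breakpoints, in days.
#' @return An object of class `pem_config`.
#' @export
pem_config <- function(breakpoints = c(7, 28, 63)) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) &&
    (any(breakpoints <= 0) || any(diff(breakpoints) <= 0))) {
    stop_input("breakpoints must be strictly increasing and positive")
  }
  structure(
    list(
      breakpoints = breakpoints,
      n_intervals = length(breakpoints) + 1L,
      lower = c(0, breakpoints),
      upper = c(breakpoints, Inf)
    ),
    class = "pem_config"
  )
}

#' @export
print.pem_config <- function(x, ...) {
  cat(
    "<pem_config>", x$n_intervals, "intervals; breaks at",
    paste(x$breakpoints, collapse = ", "), "days\n"
  )
  invisible(x)
}

#' Interval membership of event times
#'
#' Half-open convention: a time exactly at a breakpoint belongs to the
#' later interval.
#'
#' @param t Numeric vector of times (days, > 0 for events).
#' @param config A [pem_config()].
#' @return Integer vector of 1-based interval indices.
#' @export
pem_interval_index <- function(t, config) {
  findInterval(t, config$lower)
}

#' Per-interval exposure times
#'
#' `Delta_i(t)`: the length of the overlap of `[0, t)` with interval i.
#' Multiplying by the interval hazards and summing gives the cumulative
#' hazard at t.
#'
#' @param t Numeric vector of times (days, >= 0).
#' @param config A [pem_config()].
#' @return `length(t) x n_intervals` matrix of exposures.
#' @export
pem_exposure <- function(t, config) {
  if (any(t < 0)) stop_input("exposure times must be nonnegative")
  lo <- config$lower
  hi <- config$upper
  out <- matrix(0, length(t), config$n_intervals)
  for (i in seq_len(config$n_intervals)) {
    out[, i] <- pmax(0, pmin(t, hi[i]) - lo[i])
  }
  out
}

#' Per-interval log hazards for episodes
#'
#' The quilt linear predictor: for episode n in cohort cell kappa, interval
#' i, `log lambda_ni = alpha_i(kappa) + beta_i(kappa)' x_n +
#' gamma_i(kappa)' I_n`, where x is the binary design row and I the
#' 10-entry treatment covariate vector.
#'
#' @param alpha `n_cells x n_intervals` materialized intercepts.
#' @param beta `n_cells x (p * n_intervals)` materialized slopes, interval
#'   blocks of p columns.
#' @param gamma `n_cells x (10 * n_intervals)` materialized treatment
#'   coefficients, interval blocks of 10 columns (constrained scale).
#' @param x Binary design matrix (`n x p`).
#' @param treat Treatment covariate matrix (`n x 10`).
#' @param cell Integer vector of 1-based cell ids per episode.
#' @return `n x n_intervals` matrix of log hazards.
#' @export
pem_log_hazard <- function(alpha, beta, gamma, x, treat, cell) {
  n <- length(cell)
  nI <- ncol(alpha)
  p <- ncol(x)
  if (ncol(beta) != p * nI) stop_input("beta has %d columns; expected %d", ncol(beta), p * nI)
  if (ncol(treat) != 10L || ncol(gamma) != 10L * nI) {
    stop_input("treatment covariate block must have 10 entries per interval")
  }
  out <- matrix(0, n, nI)
  for (i in seq_len(nI)) {
    bi <- beta[cell, ((i - 1L) * p + 1L):(i * p), drop = FALSE]
    gi <- gamma[cell, ((i - 1L) * 10L + 1L):(i * 10L), drop = FALSE]
    out[, i] <- alpha[cell, i] + rowSums(x * bi) + rowSums(treat * gi)
  }
  out
}

#' PEM log likelihood of right-censored wait times
#'
#' Event episodes contribute `log lambda(T) - sum_i lambda_i Delta_i(T)`;
#' censored episodes contribute the log survival probability
#' `-sum_i lambda_i Delta_i(T)`.
#'
#' @param time Positive wait times in days.
#' @param event 0/1 event indicators (1 = readmission-or-death observed).
#' @param log_hazards `n x n_intervals` matrix (or a single vector recycled
#'   across episodes) of per-interval log hazards.
#' @param config A [pem_config()].
#' @return Numeric vector of per-episode log likelihood contributions.
#' @export
pem_log_likelihood <- function(time, event, log_hazards, config) {
  if (any(time <= 0)) stop_input("wait times must be positive (floor same-day events upstream)")
  if (!all(event %in% c(0, 1))) stop_input("event indicator must be 0/1")
  if (is.null(dim(log_hazards))) {
    log_hazards <- matrix(log_hazards, length(time), config$n_intervals, byrow = TRUE)
  }
  lam <- exp(log_hazards)
  cumhaz <- rowSums(lam * pem_exposure(time, config))
  idx <- pem_interval_index(time, config)
  loglam_at_t <- log_hazards[cbind(seq_along(time), idx)]
  event * loglam_at_t - cumhaz
}

#' PEM survival function
#'
#' `S(t) = exp(-integral of the piecewise-constant hazard over [0, t))`;
#' `S(0) = 1`.
#'
#' @param t Nonnegative times (days).
#' @param log_hazards Vector of per-interval log hazards (single episode) or
#'   an `n x n_intervals` matrix with `length(t) == n`.
#' @param config A [pem_config()].
#' @return Survival probabilities in (0, 1].
#' @export
pem_survival <- function(t, log_hazards, config) {
  if (any(t < 0)) stop_input("survival times must be nonnegative")
  if (is.null(dim(log_hazards))) {
    log_hazards <- matrix(log_hazards, length(t), config$n_intervals, byrow = TRUE)
  }
  exp(-rowSums(exp(log_hazards) * pem_exposure(t, config)))
}

#' Event risk within a horizon
#'
#' `1 - S(horizon)`: the probability of readmission or death within the
#' first `horizon` days; the classification score behind 30- and 90-day
#' AUROC/AUPRC.
#'
#' @param horizon Positive horizon in days (scalar).
#' @param log_hazards As in [pem_survival()].
#' @param config A [pem_config()].
#' @return Risk probabilities.
#' @export
pem_event_risk <- function(horizon, log_hazards, config) {
  if (length(horizon) != 1L || horizon <= 0) stop_input("horizon must be a positive scalar")
  n <- if (is.null(dim(log_hazards))) 1L else nrow(log_hazards)
  1 - pem_survival(rep(horizon, n), log_hazards, config)
}

#' Sample wait times from a PEM
#'
#' Inverse-CDF sampling: draw a unit exponential and invert the piecewise
#' linear cumulative hazard.
#'
#' @param log_hazards `n x n_intervals` matrix of per-episode log hazards.
#' @param config A [pem_config()].
#' @return Numeric vector of event times (possibly beyond the last break).
#' @export
pem_sample_time <- function(log_hazards, config) {
  n <- nrow(log_hazards)
  lam <- exp(log_hazards)
  e <- stats::rexp(n)
  widths <- diff(c(config$lower, Inf))
  nI <- config$n_intervals
  t_out <- numeric(n)
  rem <- e
  done <- rep(FALSE, n)
  for (i in seq_len(nI)) {
    h_in_interval <- lam[, i] * widths[i]
    finishes <- !done & (rem <= h_in_interval | i == nI)
    t_out[finishes] <- config$lower[i] + rem[finishes] / lam[finishes, i]
    done <- done | finishes
    rem <- rem - h_in_interval
  }
  t_out
}
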
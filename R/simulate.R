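#' Configuration of the synthetic claims-like episode generator
#'
#' The generator emulates the engineered post-processing structure of
#' inpatient claims data: sparse heavy-tailed utilization counts loading on
#' a latent health score, binarization by quantile-style cutoffs, a small
#' cohort lattice of discrete admission attributes, acuity-ordered
#' discharge placement confounded with latent health, and right-censored
#' wait times from the piecewise exponential hazard — with every true
#' parameter recorded so recovery is checkable.
#'
#' Defaults define the shipped study scenario: 20,000 episodes, 10
#' binarized features, a 2x2 cohort lattice, four hazard intervals with
#' breaks at 7/28/63 days, a 90-day censoring window, and baseline hazards
#' calibrated so about 20% of episodes are readmitted or die within 30
#' days (roughly 17% readmission + 3% death).
#'
#' @param n Episodes.
#' @param p Raw count features (one binary design column each).
#' @param dispersion Gamma-Poisson overdispersion of the counts (variance
#'   of the multiplicative gamma noise; larger = heavier tails).
#' @param attr_cards Cardinalities of the discrete cohort attributes
#'   (default `c(2, 2)`, a 2x2 lattice).
#' @param breakpoints PEM breakpoints in days.
#' @param confounding_strength Weight of latent health in the placement
#'   linear predictor.
#' @param health_hazard_weight Weight of latent health in the log hazard.
#'   The default 0 keeps the outcome model well-specified (health reaches
#'   the hazard only through its observable feature proxies), so parameter
#'   recovery is a clean test of inference; [sim_config_confounded()] turns
#'   the unobserved pathway on.
#' @param target_event_rate Target 30-day event fraction; baseline
#'   intercepts are shifted to hit it (NULL = no calibration).
#' @param censor_days Administrative censoring window (days, > 30).
#' @param true_params Optional list overriding the planted true parameters:
#'   `alpha` (`n_cells x n_intervals`), `beta` (`n_cells x (p*n_intervals)`),
#'   `gamma_ind` (`n_cells x (5*n_intervals)`, must be <= 0), `cutpoints`
#'   (length 5, increasing), `xi` (length p). Defaults are planted sparse
#'   effects with mild cohort variation.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `quilt_sim_config` list.
#' @export
sim_config <- function(n = 20000L, p = 10L, dispersion = 1.5,
                       attr_cards = c(2L, 2L), breakpoints = c(7, 28, 63),
                       confounding_strength = 1, health_hazard_weight = 0,
                       target_event_rate = 0.20, censor_days = 90,
                       true_params = list(), seed = 1L) {
  stopifnot(n >= 1, p >= 1, dispersion >= 0, confounding_strength >= 0)
  if (censor_days <= 30) stop_input("censoring window must exceed 30 days")
  pem <- pem_config(breakpoints)
  nI <- pem$n_intervals
  ncell <- prod(attr_cards)

  defaults <- sim_default_params(p, nI, ncell, seed)
  tp <- utils::modifyList(defaults, true_params)
  if (any(tp$gamma_ind > 0)) stop_input("true gamma_ind effects must be <= 0")
  if (any(diff(tp$cutpoints) <= 0)) stop_input("true cutpoints must be increasing")

  structure(
    list(
      n = as.integer(n), p = as.integer(p), dispersion = dispersion,
      attr_cards = as.integer(attr_cards), pem = pem,
      confounding_strength = confounding_strength,
      health_hazard_weight = health_hazard_weight,
      target_event_rate = target_event_rate, censor_days = censor_days,
      true_params = tp, seed = as.integer(seed)
    ),
    class = "quilt_sim_config"
  )
}

# Planted true parameters: interval-decaying baselines; a sparse set of
# positive/negative feature log hazard ratios with mild cohort variation;
# monotone non-positive placement effects; placement-model slopes on the
# first features.
sim_default_params <- function(p, nI, ncell, seed) {
  set.seed(derive_seed(seed, 17L))
  base_alpha <- c(-3.6, -4.4, -4.9, -5.4)[seq_len(nI)]
  alpha <- matrix(rep(base_alpha, each = ncell), ncell, nI) +
    matrix(stats::rnorm(ncell * nI, 0, 0.25), ncell, nI)

  n_signal <- max(1L, min(4L, p))
  beta_core <- numeric(p)
  beta_core[seq_len(n_signal)] <- c(0.7, -0.5, 0.5, -0.4)[seq_len(n_signal)]
  beta <- matrix(0, ncell, p * nI)
  for (i in seq_len(nI)) {
    fade <- c(1, 0.8, 0.6, 0.5)[i]
    block <- matrix(rep(beta_core * fade, each = ncell), ncell, p) +
      matrix(stats::rnorm(ncell * p, 0, 0.1), ncell, p) *
        rep(beta_core != 0, each = ncell)
    beta[, ((i - 1) * p + 1):(i * p)] <- block
  }

  gamma_core <- c(-0.15, -0.3, -0.45, -0.55, -0.65)
  gamma_ind <- matrix(0, ncell, 5 * nI)
  for (i in seq_len(nI)) {
    gamma_ind[, ((i - 1) * 5 + 1):(i * 5)] <-
      matrix(rep(gamma_core, each = ncell), ncell, 5) *
        c(1, 0.8, 0.6, 0.5)[i] -
      matrix(stats::runif(ncell * 5, 0, 0.1), ncell, 5)
  }

  xi <- numeric(p)
  xi[seq_len(min(3L, p))] <- c(0.6, -0.4, 0.5)[seq_len(min(3L, p))]

  list(
    alpha = alpha, beta = beta, gamma_ind = gamma_ind,
    cutpoints = c(-1, -0.2, 0.6, 1.4, 2.2), xi = xi
  )
}

#' Simulate a claims-like episode dataset with known ground truth
#'
#' @param config A [sim_config()].
#' @return A list: `data` (tibble of raw counts `f1..fp`, cohort attribute
#'   columns `a1..`, `placement`, `time`, `event`), `truth` (true
#'   parameters materialized per cohort, per-episode exceedance
#'   probabilities, true 30-day risks, latent health, the binary design and
#'   its cutoff table), and `lattice`.
#' @export
simulate_episodes <- function(config) {
  stopifnot(inherits(config, "quilt_sim_config"))
  set.seed(config$seed)
  n <- config$n
  p <- config$p
  nI <- config$pem$n_intervals
  tp <- config$true_params

  # latent health: higher = sicker
  health <- stats::rnorm(n)

  # sparse heavy-tailed counts loading on health (gamma-mixed Poisson)
  mu <- exp(stats::runif(p, log(0.7), log(3)))
  load <- stats::runif(p, 0.2, 0.8) * sample(c(-1, 1), p, replace = TRUE, prob = c(0.3, 0.7))
  shape <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  counts <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    g <- if (is.finite(shape)) stats::rgamma(n, shape = shape, rate = shape) else 1
    counts[, j] <- stats::rpois(n, lambda = mu[j] * g * exp(load[j] * health))
  }
  colnames(counts) <- paste0("f", seq_len(p))

  # binarization: one cutoff per feature at max(1, type-1 median), kept as
  # a regular cutoff table so the featurization pipeline reapplies it
  cuts <- lapply(seq_len(p), function(j) {
    max(1, unname(stats::quantile(counts[, j], 0.5, type = 1)))
  })
  names(cuts) <- colnames(counts)
  cutoffs <- structure(
    list(cutoffs = cuts, probs = 0.5, dropped = rep(FALSE, p)),
    class = "quilt_cutoffs"
  )
  Xb <- binarize(counts, cutoffs)

  # cohort lattice from discrete attributes
  attrs <- vapply(
    config$attr_cards,
    function(k) sample.int(k, n, replace = TRUE) - 1L, integer(n)
  )
  colnames(attrs) <- paste0("a", seq_along(config$attr_cards))
  lattice <- quilt_lattice(stats::setNames(config$attr_cards, colnames(attrs)))
  cell <- cell_id(lattice, attrs)

  # placement: proportional odds with latent-health confounding
  eta <- as.vector(Xb %*% tp$xi) + config$confounding_strength * health
  op <- ordinal_probs(eta, tp$cutpoints)
  u <- stats::runif(n)
  cum <- t(apply(op$probs, 1, cumsum))
  placement <- as.integer(rowSums(u > cum)) # 0..5
  ind <- outer(placement, 1:5, ">=") * 1

  # hazard: cohort baselines + feature effects + received-placement
  # effects + the unobserved health pathway
  LH <- matrix(0, n, nI)
  for (i in seq_len(nI)) {
    bi <- tp$beta[cell, ((i - 1) * p + 1):(i * p), drop = FALSE]
    gi <- tp$gamma_ind[cell, ((i - 1) * 5 + 1):(i * 5), drop = FALSE]
    LH[, i] <- tp$alpha[cell, i] + rowSums(Xb * bi) + rowSums(ind * gi) +
      config$health_hazard_weight * health
  }

  # calibrate a common intercept offset to the target 30-day event rate
  offset <- 0
  if (!is.null(config$target_event_rate)) {
    tgt <- config$target_event_rate
    if (tgt <= 0 || tgt >= 1) stop_input("target event rate must be in (0, 1)")
    Lam30 <- rowSums(exp(LH) * pem_exposure(rep(30, n), config$pem))
    f <- function(o) mean(1 - exp(-exp(o) * Lam30)) - tgt
    lo_ok <- f(-12) < 0
    hi_ok <- f(8) > 0
    if (!lo_ok || !hi_ok) {
      stop_input(
        "target event rate %.3f unachievable; achievable range (%.4f, %.4f)",
        tgt, mean(1 - exp(-exp(-12) * Lam30)), mean(1 - exp(-exp(8) * Lam30))
      )
    }
    offset <- stats::uniroot(f, c(-12, 8), tol = 1e-10)$root
    LH <- LH + offset
    tp$alpha <- tp$alpha + offset
  }

  t_event <- pem_sample_time(LH, config$pem)
  time <- pmin(t_event, config$censor_days)
  event <- as.numeric(t_event < config$censor_days)
  time <- pmax(time, 0.5)

  risk30 <- 1 - pem_survival(rep(30, n), LH, config$pem)

  data <- tibble::as_tibble(as.data.frame(counts))
  for (j in seq_len(ncol(attrs))) data[[colnames(attrs)[j]]] <- attrs[, j]
  data$placement <- placement
  data$time <- time
  data$event <- event

  truth <- list(
    params = tp, alpha_offset = offset, lattice = lattice, cell = cell,
    cutoffs = cutoffs, design = Xb, design_cols = colnames(Xb),
    exceedance = op$exceedance, probs = op$probs,
    risk30 = risk30, health = health, log_hazard = LH,
    feature_loadings = load
  )
  list(data = data, truth = truth, lattice = lattice)
}

#' Unadjusted placement log-rate contrasts
#'
#' The naive single-interval exponential estimate of each placement's
#' effect: log of the event rate (events / person-days of exposure) in
#' placement k over the rate in placement 0, ignoring all covariates.
#' Under confounded selection this contrast is biased relative to the true
#' effect; it is the baseline the joint model's adjustment is measured
#' against.
#'
#' @param data Data frame with `placement`, `time`, `event` columns.
#' @return A tibble: placement, events, exposure, rate, contrast (log rate
#'   ratio vs placement 0; NA when a category has no exposure or events,
#'   with a warning).
#' @export
naive_effect_contrast <- function(data) {
  data <- as.data.frame(data)
  if (length(unique(data$placement)) < 2L) {
    stop_input("need at least two placement categories")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$placement),
    events = sum(.data$event), exposure = sum(.data$time), .groups = "drop"
  )
  agg <- dplyr::arrange(agg, .data$placement)
  agg$rate <- ifelse(agg$exposure > 0, agg$events / agg$exposure, NA_real_)
  bad <- agg$exposure <= 0 | agg$events == 0
  if (any(bad)) {
    warning("placement categories with zero exposure or events: contrasts undefined")
    agg$rate[agg$events == 0] <- NA_real_
  }
  r0 <- agg$rate[agg$placement == 0]
  if (length(r0) != 1L || is.na(r0)) stop_input("reference placement 0 has no usable rate")
  agg$contrast <- log(agg$rate / r0)
  agg
}

#' The planted-confounding scenario
#'
#' A [sim_config()] variant with an unobserved latent-health pathway into
#' the hazard: latent health raises both the acuity of the assigned
#' placement and the event hazard itself, so unadjusted placement
#' contrasts overstate harm. The benchmark for the joint model's
#' confounding adjustment.
#'
#' The scenario uses a single-interval wait-time model (no breakpoints), so
#' the naive exponential-rate contrast and the model's placement effects
#' target the same estimand, and a richer, less dispersed feature set
#' (p = 20, dispersion 0.8): the adjustment operates through observables
#' that proxy latent health, so the benchmark gives it proxies to use.
#'
#' @param n Episodes.
#' @param health_hazard_weight Strength of the unobserved hazard pathway.
#' @param confounding_strength Weight of latent health in placement.
#' @param p Count features (richer than the base scenario).
#' @param dispersion Count overdispersion (lower = cleaner proxies).
#' @param breakpoints PEM breakpoints (none: single interval).
#' @param seed Integer seed.
#' @param ... Passed on to [sim_config()].
#' @return A `quilt_sim_config`.
#' @export
sim_config_confounded <- function(n = 6000L, health_hazard_weight = 0.7,
                                  confounding_strength = 1.2, p = 20L,
                                  dispersion = 0.8, breakpoints = numeric(0),
                                  seed = 1L, ...) {
  sim_config(
    n = n, health_hazard_weight = health_hazard_weight,
    confounding_strength = confounding_strength, p = p,
    dispersion = dispersion, breakpoints = breakpoints, seed = seed, ...
  )
}
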
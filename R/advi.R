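#' Training configuration for stochastic variational inference
#'
#' Defaults follow the reference optimizer schedule for full-scale fits:
#' minibatches of 10^4 episodes (capped at the dataset size), 8 Monte Carlo
#' parameter samples per ELBO evaluation, Adam with starting learning rate
#' 0.0015 wrapped in a lookahead optimizer, a 10% learning-rate decay on
#' every epoch whose mean batch loss fails to improve, stopping after 5
#' non-improving epochs or 100 epochs. Desk-scale fits typically pass a
#' smaller `batch_size` (more gradient steps per epoch) and a larger `lr`.
#'
#' @param batch_size Minibatch size (capped at n during fitting).
#' @param mc_samples Monte Carlo samples per ELBO/gradient evaluation.
#' @param lr Initial Adam learning rate.
#' @param decay Learning-rate multiplier applied on a non-improving epoch.
#' @param patience Consecutive non-improving epochs before stopping.
#' @param max_epochs Epoch cap.
#' @param lookahead_sync Lookahead synchronization period (steps).
#' @param lookahead_alpha Lookahead slow-weights interpolation factor.
#' @param improve_tol Minimum decrease of epoch-mean loss that counts as
#'   improvement (default 0: any decrease).
#' @param init_loc_sd Std. dev. of the random initialization of variational
#'   locations.
#' @param init_log_scale Initial variational log scales.
#' @param seed Integer seed controlling initialization, batching, and MC
#'   draws; fits are bit-reproducible given the seed.
#' @return A `quilt_train_config` list.
#' @export
quilt_train_config <- function(batch_size = 1e4, mc_samples = 8L, lr = 0.0015,
                               decay = 0.9, patience = 5L, max_epochs = 100L,
                               lookahead_sync = 6L, lookahead_alpha = 0.5,
                               improve_tol = 0, init_loc_sd = 0.01,
                               init_log_scale = -3, seed = 1L) {
  stopifnot(
    batch_size >= 1, mc_samples >= 1, lr > 0, decay > 0, decay < 1,
    patience >= 1, patience <= max_epochs, lookahead_sync >= 1,
    lookahead_alpha > 0, lookahead_alpha <= 1
  )
  structure(
    list(
      batch_size = batch_size, mc_samples = as.integer(mc_samples), lr = lr,
      decay = decay, patience = as.integer(patience),
      max_epochs = as.integer(max_epochs),
      lookahead_sync = as.integer(lookahead_sync),
      lookahead_alpha = lookahead_alpha, improve_tol = improve_tol,
      init_loc_sd = init_loc_sd, init_log_scale = init_log_scale,
      seed = as.integer(seed)
    ),
    class = "quilt_train_config"
  )
}

# One Adam update; state carries first/second moments and step count.
adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$theta <- state$theta - lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Fit a quilt model by minibatch mean-field variational inference
#'
#' Optimizes a fully factorized Gaussian over the unconstrained latents by
#' stochastic reparameterized ELBO ascent with analytic gradients of the
#' joint density. The negative ELBO ("loss") is tracked per epoch; the
#' learning rate decays whenever the epoch-mean loss fails to improve on
#' the best seen, and training stops after `patience` consecutive
#' non-improving epochs or `max_epochs`.
#'
#' @param model A [quilt_model()].
#' @param config A [quilt_train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `quilt_fit`: variational locations `mu` and
#'   log scales `omega`, the bound model, the training trace (a tibble of
#'   epoch, loss, learning rate), and the config.
#' @export
quilt_fit <- function(model, config = quilt_train_config(), verbose = FALSE) {
  stopifnot(inherits(model, c("quilt_model", "advi_problem")))
  m <- model$n_latent
  n <- model$n
  B <- as.integer(min(config$batch_size, n))
  set.seed(config$seed)
  density_grad <- if (inherits(model, "quilt_model")) {
    function(z, batch) qm_density_grad(model, z, batch)
  } else {
    function(z, batch) model$density_grad(z, batch)
  }

  mu <- stats::rnorm(m, 0, config$init_loc_sd)
  if (inherits(model, "quilt_model")) {
    # zero-order baseline terms start at the marginal per-interval log rates
    a_off <- model$layout$alpha$offset
    a_rows <- model$dps$alpha$n_rows
    mu[a_off + (seq_len(model$n_intervals) - 1L) * a_rows + 1L] <-
      mu[a_off + (seq_len(model$n_intervals) - 1L) * a_rows + 1L] + model$init_alpha
  }
  omega <- rep(config$init_log_scale, m)
  theta <- c(mu, omega)
  state <- list(theta = theta, m = numeric(2 * m), v = numeric(2 * m), t = 0L)
  slow <- theta
  lr <- config$lr

  entropy_const <- 0.5 * m * log(2 * pi * exp(1))
  trace <- list()
  best <- Inf
  bad <- 0L
  step <- 0L
  epochs_run <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    n_batches <- ceiling(n / B)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      batch <- perm[((bi - 1L) * B + 1L):min(bi * B, n)]
      mu <- state$theta[1:m]
      omega <- state$theta[(m + 1):(2 * m)]
      sigma <- exp(omega)
      g_mu <- numeric(m)
      g_om <- numeric(m)
      val <- 0
      for (s in seq_len(config$mc_samples)) {
        eps <- stats::rnorm(m)
        zdraw <- mu + sigma * eps
        dg <- density_grad(zdraw, batch)
        val <- val + dg$value
        g_mu <- g_mu + dg$grad
        g_om <- g_om + dg$grad * eps * sigma
      }
      S <- config$mc_samples
      elbo <- val / S + sum(omega) + entropy_const
      loss <- -elbo
      grad_theta <- -c(g_mu / S, g_om / S + 1)
      state <- adam_step(state, grad_theta, lr)
      step <- step + 1L
      if (step %% config$lookahead_sync == 0L) {
        slow <- slow + config$lookahead_alpha * (state$theta - slow)
        state$theta <- slow
      }
      epoch_loss <- epoch_loss + loss
    }
    epoch_loss <- epoch_loss / n_batches
    trace[[epoch]] <- c(epoch = epoch, loss = epoch_loss, lr = lr)
    epochs_run <- epoch
    if (verbose) {
      message(sprintf("epoch %3d  loss %.3f  lr %.5f", epoch, epoch_loss, lr))
    }
    if (epoch_loss < best - config$improve_tol) {
      best <- epoch_loss
      bad <- 0L
    } else {
      bad <- bad + 1L
      lr <- lr * config$decay
    }
    if (bad >= config$patience) break
  }

  theta <- slow
  trace_df <- tibble::as_tibble(do.call(rbind, trace))
  structure(
    list(
      model = model, mu = theta[1:m], omega = theta[(m + 1):(2 * m)],
      trace = trace_df, config = config,
      epochs = epochs_run, final_loss = trace_df$loss[nrow(trace_df)],
      converged = bad >= config$patience
    ),
    class = "quilt_fit"
  )
}

#' @export
print.quilt_fit <- function(x, ...) {
  cat(sprintf(
    "<quilt_fit> %d latents; %d epochs (%s); final loss %.2f\n",
    length(x$mu), x$epochs,
    if (x$converged) "stopped on patience" else "hit epoch cap",
    x$final_loss
  ))
  invisible(x)
}

#' Draw constrained cell-level parameter arrays from the posterior
#'
#' Each draw materializes every lattice-varying parameter on its
#' constrained scale: `A` (baseline log hazards, cells x intervals), `B`
#' (feature log hazard ratios, cells x (p x intervals)), `GP` / `GI`
#' (placement probability-block and non-positive indicator-block
#' coefficients, cells x (5 x intervals)), `CUT` (ordered cutpoints,
#' cells x 5), and `XI` (placement-model slopes, cells x p).
#'
#' @param fit A [quilt_fit()].
#' @param n_draws Number of posterior draws.
#' @param seed Seed for the draws.
#' @return A list of length `n_draws` of named matrix lists.
#' @export
posterior_draw_arrays <- function(fit, n_draws = 200L, seed = 1L) {
  set.seed(as.integer(seed))
  m <- length(fit$mu)
  sigma <- exp(fit$omega)
  lapply(seq_len(n_draws), function(s) {
    zdraw <- fit$mu + sigma * stats::rnorm(m)
    cp <- qm_constrain(fit$model, zdraw)
    cp[c("A", "B", "GP", "GI", "CUT", "XI")]
  })
}

#' Posterior-mean constrained parameter arrays
#'
#' Monte Carlo average of [posterior_draw_arrays()]: the posterior-mean
#' materialized parameters on the constrained scale.
#'
#' @inheritParams posterior_draw_arrays
#' @return A named list of matrices (see [posterior_draw_arrays()]).
#' @export
posterior_mean_arrays <- function(fit, n_draws = 200L, seed = 1L) {
  draws <- posterior_draw_arrays(fit, n_draws, seed)
  out <- draws[[1]]
  for (nm in names(out)) {
    out[[nm]] <- Reduce(`+`, lapply(draws, `[[`, nm)) / length(draws)
  }
  out
}

#' Posterior summaries of all constrained model parameters
#'
#' Monte Carlo summaries (mean, sd, central 95% interval) of every
#' materialized parameter on its constrained scale: baseline log hazards
#' per cohort and interval, feature log hazard ratios, placement effects
#' (exceedance-probability block and the non-positive indicator block),
#' ordinal cutpoints, and placement-model slopes.
#'
#' @param fit A [quilt_fit()].
#' @param n_draws Number of posterior draws (>= 2; default 200).
#' @param seed Seed for the draws.
#' @return A tibble with columns `block`, `cell`, `cohort`, `interval`,
#'   `term`, `mean`, `sd`, `lower`, `upper`.
#' @export
posterior_summary <- function(fit, n_draws = 200L, seed = 1L) {
  if (n_draws < 2) stop_input("n_draws must be at least 2")
  draws <- posterior_draw_arrays(fit, n_draws, seed)
  model <- fit$model
  nI <- model$n_intervals
  p <- model$p
  ncell <- n_cells(model$lattice)
  km <- cell_multi_index(model$lattice, seq_len(ncell))
  cohort_lab <- apply(km, 1, paste, collapse = ",")
  int_lab <- interval_labels(model$pem)
  feats <- model$features

  summarize_block <- function(name, term_of_col, interval_of_col) {
    mats <- lapply(draws, `[[`, name)
    nc <- ncol(mats[[1]])
    flat <- vapply(mats, as.vector, numeric(ncell * nc)) # entries x draws
    tibble::tibble(
      block = name_map[[name]],
      cell = rep(seq_len(ncell), nc),
      cohort = rep(cohort_lab, nc),
      interval = rep(interval_of_col, each = ncell),
      term = rep(term_of_col, each = ncell),
      mean = rowMeans(flat),
      sd = apply(flat, 1, stats::sd),
      lower = apply(flat, 1, stats::quantile, probs = 0.025),
      upper = apply(flat, 1, stats::quantile, probs = 0.975)
    )
  }
  name_map <- list(
    A = "baseline", B = "feature", GP = "placement_prob",
    GI = "placement_effect", CUT = "cutpoint", XI = "placement_slope"
  )
  place_lab <- paste0("I>=", 1:5)
  out <- dplyr::bind_rows(
    summarize_block("A", rep("(intercept)", nI), int_lab),
    summarize_block("B", rep(feats, nI), rep(int_lab, each = p)),
    summarize_block("GP", rep(paste0("Pr(", place_lab, ")"), nI), rep(int_lab, each = 5)),
    summarize_block("GI", rep(place_lab, nI), rep(int_lab, each = 5)),
    summarize_block("CUT", paste0("c_", 1:5), rep(NA_character_, 5)),
    summarize_block("XI", feats, rep(NA_character_, p))
  )
  out
}

interval_labels <- function(pem) {
  lo <- pem$lower
  hi <- pem$upper
  vapply(seq_len(pem$n_intervals), function(i) {
    if (is.finite(hi[i])) sprintf("[%g,%g)d", lo[i], hi[i]) else sprintf("%g+d", lo[i])
  }, character(1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior coefficient summaries of a quilt fit
#'
#' @param x A [quilt_fit()].
#' @param n_draws,seed Passed to [posterior_summary()].
#' @param ... Unused.
#' @return The [posterior_summary()] tibble.
#' @method tidy quilt_fit
#' @export
tidy.quilt_fit <- function(x, n_draws = 200L, seed = 1L, ...) {
  posterior_summary(x, n_draws = n_draws, seed = seed)
}

#' One-row fit summary of a quilt fit
#' @param x A [quilt_fit()].
#' @param ... Unused.
#' @return A one-row tibble: episodes, cells, latents, epochs, final loss,
#'   convergence flag.
#' @method glance quilt_fit
#' @export
glance.quilt_fit <- function(x, ...) {
  tibble::tibble(
    n = x$model$n, n_cells = n_cells(x$model$lattice),
    n_latent = x$model$n_latent, epochs = x$epochs,
    loss = x$final_loss, converged = x$converged
  )
}

#' Predicted event risks at a horizon
#'
#' Computes each episode's per-interval posterior-mean log hazard (plugging
#' the posterior-mean exceedance probabilities into the treatment block)
#' and returns `1 - S(horizon)`.
#'
#' @param fit A [quilt_fit()].
#' @param data Data frame with the model's feature, placement and cohort
#'   columns (defaults to the training data when NULL).
#' @param horizon Risk horizon in days (default 30).
#' @param n_draws,seed Monte Carlo settings for the posterior mean.
#' @return Numeric vector of risks in (0, 1).
#' @export
quilt_risk <- function(fit, data = NULL, horizon = 30, n_draws = 100L, seed = 1L) {
  model <- fit$model
  pm <- posterior_mean_arrays(fit, n_draws, seed)
  if (is.null(data)) {
    X <- model$X
    cell <- model$cell
    ind <- model$ind_block
  } else {
    data <- as.data.frame(data)
    X <- as.matrix(data[model$features])
    kappa <- as.matrix(data[model$cohorts])
    storage.mode(kappa) <- "integer"
    cell <- cell_id(model$lattice, kappa)
    iv <- as.integer(data[[model$placement_col]])
    ind <- outer(iv, 1:5, ">=") * 1
  }
  eta <- rowSums(X * pm$XI[cell, , drop = FALSE])
  P <- stats::plogis(eta - pm$CUT[cell, , drop = FALSE])
  W <- cbind(P, ind)
  LH <- pem_log_hazard(pm$A, pm$B, cbind_gamma(pm$GP, pm$GI, model$n_intervals), X, W, cell)
  pem_event_risk(horizon, LH, model$pem)
}

# interleave GP and GI interval blocks into the 10-per-interval layout
# pem_log_hazard expects ([P block, indicator block] per interval).
cbind_gamma <- function(GP, GI, nI) {
  cols <- lapply(seq_len(nI), function(i) {
    cbind(
      GP[, ((i - 1) * 5 + 1):(i * 5), drop = FALSE],
      GI[, ((i - 1) * 5 + 1):(i * 5), drop = FALSE]
    )
  })
  do.call(cbind, cols)
}

#' Define a generic minibatch variational problem
#'
#' Wraps an arbitrary differentiable joint log density so [quilt_fit()]
#' can optimize it with the same stochastic schedule used for quilt
#' models. Mainly a verification surface: closed-form posteriors (e.g.
#' conjugate normal means) can be fit and compared analytically.
#'
#' @param n Number of observations (for minibatch scaling inside
#'   `density_grad`).
#' @param n_latent Latent dimension.
#' @param density_grad `function(z, batch)` returning `list(value, grad)`
#'   of the minibatch-scaled joint log density.
#' @return An `advi_problem` for [quilt_fit()].
#' @export
advi_problem <- function(n, n_latent, density_grad) {
  structure(
    list(
      n = as.integer(n), n_latent = as.integer(n_latent),
      density_grad = density_grad
    ),
    class = "advi_problem"
  )
}
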
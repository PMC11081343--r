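# Shared fixtures, cached per test run: the reference simulation scenario
# and its variational fit are expensive, so every test file that needs
# them draws from here.

fixture_env <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env, inherits = FALSE)
}

# Desk-scale training schedule: small batches (many steps per epoch) and a
# larger starting rate than the full-scale default; schedule shape
# (decay/patience/cap/lookahead) unchanged.
desk_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(
      batch_size = 1000, lr = 0.03, seed = seed,
      max_epochs = 100, patience = 8
    ),
    list(...)
  )
  do.call(quilt_train_config, args)
}

fixture_sim <- function() {
  with_cache("sim", simulate_episodes(sim_config(seed = 7)))
}

# model-ready frame: binary design columns + attributes + outcomes
sim_design_frame <- function(sim) {
  Xb <- binarize(sim$data, sim$truth$cutoffs)
  attr_cols <- grep("^a[0-9]+$", names(sim$data), value = TRUE)
  cbind(as.data.frame(Xb), sim$data[c(attr_cols, "placement", "time", "event")])
}

fixture_fit <- function() {
  with_cache("fit", {
    sim <- fixture_sim()
    dd <- sim_design_frame(sim)
    feats <- sim$truth$design_cols
    m <- quilt_model(dd,
      features = feats, cohorts = c("a1", "a2"),
      max_order = 2
    )
    quilt_fit(m, desk_config(1))
  })
}

fixture_posterior_means <- function() {
  with_cache("pm", posterior_mean_arrays(fixture_fit(), n_draws = 100, seed = 1))
}

# a small episode frame with binary features for model-level unit tests
toy_episodes <- function(n = 40, p = 3, seed = 1, n_attr_levels = c(2L, 3L)) {
  set.seed(seed)
  d <- as.data.frame(matrix(rbinom(n * p, 1, 0.5), n, p))
  names(d) <- paste0("b", seq_len(p))
  for (j in seq_along(n_attr_levels)) {
    d[[paste0("a", j)]] <- sample(0:(n_attr_levels[j] - 1L), n, TRUE)
  }
  d$placement <- sample(0:5, n, TRUE)
  d$time <- stats::rexp(n, 0.05)
  d$event <- stats::rbinom(n, 1, 0.6)
  d
}

toy_model <- function(n = 40, p = 3, seed = 1, ...) {
  d <- toy_episodes(n, p, seed)
  quilt_model(d,
    features = paste0("b", seq_len(p)),
    cohorts = c("a1", "a2"), ...
  )
}
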
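test_that("the generator hits its calibrated 30-day event rate and is deterministic", {
  cfg <- sim_config(n = 8000, seed = 3)
  sim <- simulate_episodes(cfg)
  d <- sim$data
  frac30 <- mean(d$event == 1 & d$time <= 30)
  se <- sqrt(0.2 * 0.8 / nrow(d))
  expect_lt(abs(frac30 - 0.20), 4 * se)
  # byte-identical regeneration under the same seed
  sim2 <- simulate_episodes(sim_config(n = 8000, seed = 3))
  expect_identical(sim$data, sim2$data)
  expect_identical(sim$truth$risk30, sim2$truth$risk30)
  # different seed differs
  sim3 <- simulate_episodes(sim_config(n = 8000, seed = 4))
  expect_false(identical(sim$data$time, sim3$data$time))
})

test_that("a null model with constant hazard matches the binomial closed form", {
  lam <- 0.006
  nI <- 4
  cfg <- sim_config(
    n = 1e5, seed = 5, target_event_rate = NULL,
    confounding_strength = 0,
    true_params = list(
      alpha = matrix(log(lam), 4, nI),
      beta = matrix(0, 4, 10 * nI),
      gamma_ind = matrix(0, 4, 5 * nI),
      xi = rep(0, 10)
    )
  )
  sim <- simulate_episodes(cfg)
  d <- sim$data
  p30 <- 1 - exp(-30 * lam)
  frac30 <- mean(d$event == 1 & d$time <= 30)
  se <- sqrt(p30 * (1 - p30) / nrow(d))
  expect_lt(abs(frac30 - p30), 3 * se)
})

test_that("zero confounding makes placement independent of latent health", {
  cfg <- sim_config(
    n = 40000, seed = 6, confounding_strength = 0,
    true_params = list(xi = rep(0, 10))
  )
  sim <- simulate_episodes(cfg)
  h <- sim$truth$health
  pl <- sim$data$placement
  for (k in sort(unique(pl))) {
    mk <- mean(h[pl == k])
    se <- sd(h[pl == k]) / sqrt(sum(pl == k))
    expect_lt(abs(mk - mean(h)), 3.5 * se)
  }
})

test_that("generated placement frequencies match the true ordinal probabilities", {
  cfg <- sim_config(n = 50000, seed = 8)
  sim <- simulate_episodes(cfg)
  freq <- tabulate(sim$data$placement + 1, 6) / nrow(sim$data)
  expected <- colMeans(sim$truth$probs)
  se <- sqrt(expected * (1 - expected) / nrow(sim$data))
  expect_true(all(abs(freq - expected) < 4 * se + 1e-8))
})

test_that("wait times follow the true piecewise exponential model (PIT check)", {
  # huge censoring window so virtually all events are observed
  cfg <- sim_config(n = 10000, seed = 9, censor_days = 1e5, target_event_rate = NULL)
  sim <- simulate_episodes(cfg)
  d <- sim$data
  obs <- d$event == 1 & d$time > 0.5 # drop the same-day floor atoms
  u <- 1 - pem_survival(d$time[obs], sim$truth$log_hazard[obs, ], cfg$pem)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("generated datasets pass the featurization and model schema unchanged", {
  cfg <- sim_config(n = 1500, seed = 10)
  sim <- simulate_episodes(cfg)
  Xb <- binarize(sim$data, sim$truth$cutoffs)
  expect_identical(Xb, sim$truth$design)
  dd <- cbind(as.data.frame(Xb), sim$data[c("a1", "a2", "placement", "time", "event")])
  expect_no_error(
    quilt_model(dd, features = colnames(Xb), cohorts = c("a1", "a2"), max_order = 1)
  )
})

test_that("an unachievable event-rate target errors with the achievable range", {
  expect_error(
    simulate_episodes(sim_config(n = 500, seed = 11, target_event_rate = 1e-8)),
    "achievable range"
  )
  expect_error(
    simulate_episodes(sim_config(n = 500, seed = 11, target_event_rate = 2)),
    "in \\(0, 1\\)"
  )
})

test_that("naive contrasts match hand-counted rates and detect the null", {
  toy <- tibble::tibble(
    placement = c(0, 0, 0, 1, 1, 2),
    time = c(10, 20, 30, 5, 15, 25),
    event = c(1, 0, 1, 1, 1, 0)
  )
  expect_warning(nec <- naive_effect_contrast(toy), "zero exposure or events")
  expect_equal(nec$rate[nec$placement == 0], 2 / 60)
  expect_equal(nec$rate[nec$placement == 1], 2 / 20)
  expect_equal(
    nec$contrast[nec$placement == 1],
    log((2 / 20) / (2 / 60))
  )
  # the event-free category is flagged undefined, not silently zero
  expect_true(is.na(nec$contrast[nec$placement == 2]))
})

test_that("no confounding and null effects give near-zero naive contrasts", {
  cfg <- sim_config(
    n = 60000, seed = 12, confounding_strength = 0,
    target_event_rate = NULL,
    true_params = list(
      alpha = matrix(-4.5, 4, 4),
      beta = matrix(0, 4, 40),
      gamma_ind = matrix(0, 4, 20),
      xi = rep(0, 10)
    )
  )
  sim <- simulate_episodes(cfg)
  nec <- naive_effect_contrast(sim$data)
  expect_true(all(abs(nec$contrast[-1]) < 0.15))
})

test_that("harmful selection makes the naive contrast overstate harm", {
  cfg <- sim_config_confounded(n = 30000, seed = 13)
  sim <- simulate_episodes(cfg)
  nec <- naive_effect_contrast(sim$data)
  true_cum <- cumsum(colMeans(matrix(sim$truth$params$gamma_ind[, 1:5], ncol = 5)))
  est <- nec$contrast[match(1:5, nec$placement)]
  # sicker patients get more acute placements and higher hazards: the
  # unadjusted contrast must sit above (less protective than) the truth
  expect_gt(mean(est - true_cum), 0.2)
})
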
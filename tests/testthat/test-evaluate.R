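test_that("AUROC and AUPRC handle separation, ties, and bad inputs", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), c(rep(1, 4), rep(0, 6))), 0.5)
  expect_error(auroc(runif(5), rep(1, 5)), "single class")
  expect_error(auprc(runif(5), c(0, 0, 2, 1, 0)), "0/1")
})

test_that("rank-statistic AUROC equals the exhaustive pairwise oracle", {
  pair_oracle <- function(s, y) {
    pos <- s[y == 1]
    neg <- s[y == 0]
    tot <- 0
    for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
    tot / (length(pos) * length(neg))
  }
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(10:300, 1)
    s <- round(runif(n), sample(1:3, 1)) # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), pair_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("average precision matches a direct sweep computation", {
  set.seed(52)
  s <- runif(50)
  y <- rbinom(50, 1, 0.3)
  ord <- order(s, decreasing = TRUE)
  yy <- y[ord]
  ap <- mean(cumsum(yy)[yy == 1] / which(yy == 1))
  expect_equal(auprc(s, y), ap, tolerance = 1e-12)
})

test_that("horizon metrics exclude unknown-status episodes and score both horizons", {
  set.seed(53)
  n <- 400
  d <- tibble::tibble(
    risk = runif(n),
    time = rexp(n, 1 / 40),
    event = rbinom(n, 1, 0.5)
  )
  hm <- horizon_metrics(d, horizons = c(30, 90))
  expect_equal(nrow(hm), 2L)
  known30 <- d$event == 1 | d$time >= 30
  expect_equal(hm$n_used[1], sum(known30))
  expect_equal(hm$n_excluded[1], n - sum(known30))
  expect_true(all(hm$auroc > 0 & hm$auroc < 1))
})

test_that("interpretation tables expose the fitted quilt in readable form", {
  fit <- local({
    d <- toy_episodes(n = 250, p = 3, seed = 54)
    m <- quilt_model(d, features = paste0("b", 1:3), cohorts = c("a1", "a2"), max_order = 1)
    quilt_fit(m, quilt_train_config(
      batch_size = 125, lr = 0.02, seed = 1, max_epochs = 10, patience = 5
    ))
  })
  cb <- cohort_baseline_table(fit, n_draws = 80)
  expect_equal(nrow(cb), n_cells(fit$model$lattice) * fit$model$n_intervals)

  te <- treatment_effect_table(fit, n_draws = 80)
  expect_true(all(te$mean <= 0))
  expect_true(all(te$sd > 0))
  expect_equal(nrow(te), n_cells(fit$model$lattice) * fit$model$n_intervals * 5)

  rf <- risk_factor_table(fit, interval = 1, top_k = 2, n_draws = 80)
  expect_equal(nrow(rf), 2L)
  expect_true(all(abs(rf$mean) >= 0))
  expect_true(all(diff(abs(rf$mean)) <= 0)) # sorted by |mean|
  expect_warning(
    rf_all <- risk_factor_table(fit, interval = 1, top_k = 99, n_draws = 80),
    "exceeds"
  )
  expect_equal(nrow(rf_all), 3L)
  expect_error(risk_factor_table(fit, interval = 9), "interval")

  # consistency with posterior_summary under the same draws/seed
  ps <- posterior_summary(fit, n_draws = 80, seed = 1)
  base_ps <- dplyr::filter(ps, block == "baseline")
  expect_equal(cb$mean, base_ps$mean, tolerance = 1e-12)

  # plot constructors return ggplot objects without evaluation errors
  expect_s3_class(plot_cohort_hazards(cb), "ggplot")
  expect_s3_class(plot_risk_factors(rf), "ggplot")
  expect_s3_class(plot_treatment_effects(te), "ggplot")
  expect_s3_class(plot_training_trace(fit), "ggplot")
  expect_s3_class(autoplot(fit, type = "trace"), "ggplot")
})

test_that("a planted dominant coefficient ranks first in the risk-factor table", {
  set.seed(55)
  cfg <- sim_config(
    n = 6000, p = 6, seed = 55, breakpoints = numeric(0),
    attr_cards = c(2L),
    true_params = list(
      alpha = matrix(-4, 2, 1),
      beta = matrix(rep(c(1.2, rep(0, 5)), each = 2), 2, 6),
      gamma_ind = matrix(-0.2, 2, 5),
      xi = rep(0, 6)
    )
  )
  sim <- simulate_episodes(cfg)
  Xb <- binarize(sim$data, sim$truth$cutoffs)
  dd <- cbind(as.data.frame(Xb), sim$data[c("a1", "placement", "time", "event")])
  m <- quilt_model(dd,
    features = colnames(Xb), cohorts = "a1",
    breakpoints = numeric(0), max_order = 1
  )
  fit <- quilt_fit(m, desk_config(55, max_epochs = 40))
  rf <- risk_factor_table(fit, interval = 1, top_k = 6, n_draws = 100)
  expect_equal(rf$term[1], "f1>=1")
  expect_gt(rf$mean[1], 0.5)
})

test_that("a planted cohort-specific baseline elevation is recovered as that cell's maximum", {
  set.seed(56)
  alpha_true <- matrix(-4.6, 4, 1)
  alpha_true[3, 1] <- -3.4 # elevated first (only) interval in cell 3
  cfg <- sim_config(
    n = 8000, seed = 56, breakpoints = numeric(0),
    target_event_rate = NULL,
    true_params = list(
      alpha = alpha_true, beta = matrix(0, 4, 10),
      gamma_ind = matrix(-0.1, 4, 5), xi = rep(0, 10)
    )
  )
  sim <- simulate_episodes(cfg)
  Xb <- binarize(sim$data, sim$truth$cutoffs)
  dd <- cbind(as.data.frame(Xb), sim$data[c("a1", "a2", "placement", "time", "event")])
  m <- quilt_model(dd,
    features = colnames(Xb), cohorts = c("a1", "a2"),
    breakpoints = numeric(0), max_order = 2
  )
  fit <- quilt_fit(m, desk_config(56, max_epochs = 40))
  cb <- cohort_baseline_table(fit, n_draws = 100)
  expect_equal(cb$cell[which.max(cb$mean)], 3)
})
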
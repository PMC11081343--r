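test_that("interval conventions are half-open with breakpoint times in the later interval", {
  cfg <- pem_config(c(7, 28, 63))
  expect_equal(cfg$n_intervals, 4L)
  expect_equal(pem_interval_index(c(0.5, 6.99, 7, 27, 28, 63, 400), cfg), c(1, 1, 2, 2, 3, 4, 4))
  expect_error(pem_config(c(7, 7)), "increasing")
  expect_error(pem_config(c(-1, 7)), "increasing")
})

test_that("exposure decomposes time into interval overlaps", {
  cfg <- pem_config(c(7, 28, 63))
  expect_equal(pem_exposure(30, cfg)[1, ], c(7, 21, 2, 0))
  expect_equal(pem_exposure(0, cfg)[1, ], c(0, 0, 0, 0))
  expect_equal(rowSums(pem_exposure(c(5, 50, 200), cfg)), c(5, 50, 200))
})

test_that("PEM log likelihood matches closed forms", {
  cfg <- pem_config(c(7, 28, 63))
  lh_const <- rep(log(0.1), 4)
  # event at T = 10 under constant hazard 0.1: log(0.1) - 1
  expect_equal(
    pem_log_likelihood(10, 1, lh_const, cfg),
    log(0.1) - 1,
    tolerance = 1e-12
  )
  # censored at T = 10: just the negative cumulative hazard
  expect_equal(pem_log_likelihood(10, 0, lh_const, cfg), -1, tolerance = 1e-12)
  # piecewise hazards, censored at 30: -(0.02*7 + 0.01*21 + 0.005*2)
  lh <- log(c(0.02, 0.01, 0.005, 0.001))
  expect_equal(pem_log_likelihood(30, 0, lh, cfg), -0.36, tolerance = 1e-12)
  expect_error(pem_log_likelihood(0, 1, lh, cfg), "positive")
})

test_that("survival and risk match the piecewise cumulative hazard", {
  cfg <- pem_config(c(7, 28, 63))
  lh <- log(c(0.02, 0.01, 0.005, 0.001))
  expect_equal(pem_survival(0, lh, cfg), 1)
  expect_equal(pem_survival(30, lh, cfg), exp(-0.36), tolerance = 1e-12)
  lh_const <- rep(log(0.1), 4)
  expect_equal(pem_survival(10, lh_const, cfg), exp(-1), tolerance = 1e-12)
  expect_equal(pem_event_risk(10, matrix(lh_const, 1), cfg), 1 - exp(-1), tolerance = 1e-12)
  # risk vanishes as hazards vanish and is nondecreasing in the horizon
  expect_lt(pem_event_risk(30, matrix(rep(-30, 4), 1), cfg), 1e-10)
  risks <- vapply(c(1, 5, 20, 40, 80, 200), function(h) {
    pem_event_risk(h, matrix(lh, 1), cfg)
  }, numeric(1))
  expect_true(all(diff(risks) >= 0))
  expect_error(pem_survival(-1, lh, cfg), "nonnegative")
})

test_that("the PEM density integrates to one and factors as hazard times survival", {
  cfg <- pem_config(c(7, 28, 63))
  set.seed(21)
  for (rep in 1:10) {
    lh <- log(runif(4, 0.001, 0.2))
    dens <- function(t) {
      vapply(t, function(ti) {
        lam <- exp(lh[pem_interval_index(ti, cfg)])
        lam * pem_survival(ti, lh, cfg)
      }, numeric(1))
    }
    total <- stats::integrate(dens, 0, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(total - 1), 1e-6)
    # density at the event time = exp(log-likelihood of an event there)
    t0 <- runif(1, 0.5, 100)
    expect_equal(exp(pem_log_likelihood(t0, 1, lh, cfg)), dens(t0), tolerance = 1e-10)
  }
})

test_that("a single interval reproduces the exponential distribution exactly", {
  cfg1 <- pem_config(numeric(0))
  set.seed(22)
  t <- rexp(200, 0.03)
  ev <- rbinom(200, 1, 0.5)
  lam <- 0.07
  ll_pem <- pem_log_likelihood(t, ev, matrix(log(lam), 200, 1), cfg1)
  ll_exp <- ev * dexp(t, lam, log = TRUE) + (1 - ev) * pexp(t, lam, lower.tail = FALSE, log.p = TRUE)
  expect_equal(ll_pem, ll_exp, tolerance = 1e-12)
})

test_that("sampled wait times follow the piecewise exponential law", {
  cfg <- pem_config(c(7, 28, 63))
  set.seed(23)
  n <- 20000
  lh <- matrix(rep(log(c(0.05, 0.02, 0.01, 0.004)), each = n), n, 4)
  ts <- pem_sample_time(lh, cfg)
  # probability integral transform: 1 - S(T) should be uniform
  u <- 1 - pem_survival(ts, lh, cfg)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-episode log hazards assemble intercept, slope, and treatment parts", {
  cfg <- pem_config(c(7, 28, 63))
  nI <- 4
  ncell <- 2
  p <- 3
  set.seed(31)
  alpha <- matrix(rnorm(ncell * nI), ncell, nI)
  beta <- matrix(rnorm(ncell * p * nI), ncell, p * nI)
  gamma <- matrix(rnorm(ncell * 10 * nI), ncell, 10 * nI)
  x <- matrix(rbinom(5 * p, 1, 0.5), 5, p)
  treat <- matrix(runif(5 * 10), 5, 10)
  cell <- c(1L, 2L, 1L, 2L, 1L)
  lh <- pem_log_hazard(alpha, beta, gamma, x, treat, cell)
  # independent scalar recomputation
  for (n_i in 1:5) {
    for (i in 1:nI) {
      expected <- alpha[cell[n_i], i] +
        sum(beta[cell[n_i], ((i - 1) * p + 1):(i * p)] * x[n_i, ]) +
        sum(gamma[cell[n_i], ((i - 1) * 10 + 1):(i * 10)] * treat[n_i, ])
      expect_equal(lh[n_i, i], expected, tolerance = 1e-12)
    }
  }
  # zero slopes: hazards equal the intercepts for every episode
  lh0 <- pem_log_hazard(
    matrix(rep(c(-3, -4, -4, -5), each = ncell), ncell, nI),
    beta * 0, gamma * 0, x, treat, cell
  )
  expect_equal(lh0, matrix(rep(c(-3, -4, -4, -5), each = 5), 5, 4), tolerance = 1e-14)
  # single-feature bump shifts only its interval
  beta1 <- beta * 0
  beta1[, 2] <- 0.2 # feature 2, interval 1
  lh1 <- pem_log_hazard(alpha, beta1, gamma * 0, x, treat, cell)
  lh_base <- pem_log_hazard(alpha, beta * 0, gamma * 0, x, treat, cell)
  expect_equal(lh1[, 1] - lh_base[, 1], 0.2 * x[, 2], tolerance = 1e-12)
  expect_equal(lh1[, 2:4], lh_base[, 2:4], tolerance = 1e-14)
})
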
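test_that("a constant series has zero conditional moments in its single bin", {
  ts <- time_series(rep(3.7, 200), dt = 0.01)
  grid <- bin_grid(seq(3, 4.4, length.out = 8), min_count = 10)
  cm <- conditional_moments(ts, lags = 1:3, grid = grid)
  occ <- which(cm$count[, 1] > 0)
  expect_length(occ, 1L)
  expect_equal(cm$M1[occ, ], rep(0, 3))
  expect_equal(cm$M2[occ, ], rep(0, 3))
  expect_equal(cm$M4[occ, ], rep(0, 3))
})

test_that("pair counts are conserved across bins and out-of-range is reported", {
  ts <- cached_sim(1000, 50, 0, n = 2e5, dt = 1e-6, seed = 15)
  grid <- default_grid(ts, bins = 20, span = 2)  # narrow: forces out-of-range
  cm <- conditional_moments(ts, lags = c(1, 7), grid = grid)
  for (j in 1:2)
    expect_equal(sum(cm$count[, j]) + cm$out_of_range[j],
                 ts$n - cm$lags[j])
  expect_gt(sum(cm$out_of_range), 0)
})

test_that("binned conditional moments agree with the OU transition oracle", {
  model <- langevin_model(1000, 50)
  ts <- cached_sim(1000, 50, 0, n = 1e7, dt = 1e-6, seed = 101)
  cm <- conditional_moments(ts, lags = 100)
  tau <- 1e-4
  ## frozen oracle values at the reference positions
  expect_equal(ou_conditional_moments(model, 0.1, tau)$mean_increment / tau,
               -95.16, tolerance = 1e-3)
  expect_equal(ou_conditional_moments(model, 0, tau)$variance / tau,
               90.63, tolerance = 1e-3)
  ## every central bin agrees with the transition-moment oracle. Nominal
  ## within-bin SEs understate the sampling error of heavily overlapping
  ## lag-100 pairs by ~3-5x (see the methods vignette), so the per-bin
  ## band is 15 nominal SEs (~3 sigma of the true scatter); the
  ## bin-averaged deviation must also stay below 0.5% of the drift range.
  sdx <- sd(ts$values)
  central <- which(abs(cm$centers) < 2 * sdx & cm$count[, 1] > 1e4)
  dev1 <- numeric(0)
  for (i in central) {
    o <- ou_conditional_moments(model, cm$centers[i], tau)
    d1 <- cm$M1[i, 1] - o$mean_increment / tau
    dev1 <- c(dev1, d1)
    expect_lt(abs(d1), 15 * cm$se1[i, 1])
    expect_lt(abs(cm$M2[i, 1] - (o$variance + o$mean_increment^2) / tau),
              15 * cm$se2[i, 1])
  }
  expect_lt(abs(mean(dev1)), 5)
})

test_that("zero-lag extrapolation recovers closed-form intercepts", {
  model <- langevin_model(1000, 50)
  lags <- 1:5
  dt <- 1e-6
  tau <- lags * dt
  centers <- seq(-0.5, 0.5, length.out = 11)
  nb <- length(centers)
  M1 <- outer(centers, tau, function(x, tt)
    ou_conditional_moments(model, x, tt)$mean_increment / tt)
  M2 <- outer(centers, tau, function(x, tt) {
    o <- ou_conditional_moments(model, x, tt)
    (o$variance + o$mean_increment^2) / tt
  })
  ones <- matrix(1, nb, length(lags))
  cm <- structure(list(count = ones * 1000, M1 = M1, M2 = M2, M4 = ones,
                       se1 = ones, se2 = ones, se4 = ones,
                       centers = centers, lags = lags, tau = tau, dt = dt,
                       min_count = 100, out_of_range = integer(5), n = 1e6),
                  class = "ot_moments")
  e1 <- suppressWarnings(extrapolate_zero_lag(cm, 1))  # exact fits
  expect_equal(e1$intercept, -1000 * centers, tolerance = 1e-4)
  e2 <- suppressWarnings(extrapolate_zero_lag(cm, 2))
  ## the finite-lag quadratic artifact in M2 extrapolates away
  expect_equal(e2$intercept / 2, rep(50, nb), tolerance = 2e-3)
  ## constant input: intercept equals the value, slope 0
  cm$M2[] <- 100
  e_const <- suppressWarnings(extrapolate_zero_lag(cm, 2))
  expect_equal(e_const$intercept, rep(100, nb), tolerance = 1e-10)
  expect_equal(e_const$slope, rep(0, nb), tolerance = 1e-6)
  cm$lags <- cm$lags[1:2]; cm$tau <- cm$tau[1:2]
  expect_error(extrapolate_zero_lag(cm, 2), "at least 3 lags")
})

test_that("the KM pipeline recovers linear-trap parameters", {
  ts <- cached_sim(5000, 50, 0, n = 1e7, dt = 1e-6, seed = 103)
  km <- cached_km(ts)
  dr <- fit_drift(km)
  df <- fit_diffusion(km)
  ## tolerances calibrated from measured seed-to-seed scatter at this n
  expect_lt(abs(dr$Q_hat - 5000) / 5000, 0.05)
  expect_lt(abs(df$a_hat - 50) / 50, 0.02)
  expect_lt(abs(df$b_hat), 20)           # no quadratic term in truth
  expect_lt(abs(dr$intercept), 20)       # drift passes through the origin
})

test_that("extrapolation removes the finite-lag quadratic diffusion artifact", {
  ts <- cached_sim(5000, 50, 0, n = 1e7, dt = 1e-6, seed = 103)
  km_no <- cached_km(ts, extrapolate = FALSE)
  km_ex <- cached_km(ts)
  b_no <- fit_diffusion(km_no)$b_hat
  b_ex <- fit_diffusion(km_ex)$b_hat
  ## at lag tau the artifact is (1 - exp(-Q tau))^2 / (2 tau) = 12.44
  predicted <- (1 - exp(-5000 * 1e-6))^2 / (2 * 1e-6)
  expect_lt(abs(b_no - predicted), 6)
  expect_lt(abs(b_ex), 8)
  expect_gt(b_no - b_ex, 5)
})

test_that("the KM pipeline recovers a quadratic diffusion law", {
  ts <- cached_sim(7100, 52, 1040, n = 1e7, dt = 1e-6, seed = 102)
  km <- cached_km(ts)
  dr <- fit_drift(km)
  df <- fit_diffusion(km)
  expect_lt(abs(dr$Q_hat - 7100) / 7100, 0.05)
  expect_lt(abs(df$a_hat - 52) / 52, 0.02)
  expect_lt(abs(df$b_hat - 1040) / 1040, 0.05)
  ## the count-weighted average sits at the stationary mean of D2(x)
  d2_avg_true <- 52 * 7100 / (7100 - 1040)
  expect_lt(abs(df$d2_average - d2_avg_true) / d2_avg_true, 0.05)
})

test_that("state-independent increments give zero drift and the Gaussian Pawula ratio", {
  set.seed(31)
  D0 <- 2; tau <- 1e-3
  x <- cumsum(rnorm(1e6, 0, sqrt(2 * D0 * tau)))   # drift-free random walk
  ts <- time_series(x, dt = tau)
  km <- km_coefficients(ts, lags = 1:3, extrapolate = FALSE)
  ## increments are independent of position: D1 = 0 in every bin
  expect_true(all(abs(km$D1) < 5 * km$se_D1))
  ## Gaussian increments: D4/D2 = D2 tau / 2 exactly in expectation
  expect_equal(pawula_ratio(km), D0 * tau / 2, tolerance = 0.1)
  expect_equal(mean(km$D2), D0, tolerance = 0.05)
})

test_that("noiseless drift and diffusion laws are fitted exactly", {
  x <- seq(-1, 1, length.out = 21)
  dr <- suppressWarnings(fit_drift(km_table(x, D1 = -5000 * x, D2 = 52 + 1040 * x^2)))
  expect_equal(dr$Q_hat, 5000, tolerance = 1e-10)
  expect_equal(dr$intercept, 0, tolerance = 1e-8)
  df <- suppressWarnings(fit_diffusion(km_table(x, D1 = -5000 * x, D2 = 52 + 1040 * x^2)))
  expect_equal(df$a_hat, 52, tolerance = 1e-10)
  expect_equal(df$b_hat, 1040, tolerance = 1e-10)
  expect_error(fit_drift(km_table(x[1:3], -x[1:3], 1 + 0 * x[1:3])), "5 usable")
})

test_that("finite-lag moment predictions match exact expansions and Monte Carlo", {
  ## linear model: closed form M1/tau = -Q x (1 - Q tau / 2)
  m <- langevin_model(1000, 50)
  p <- finite_dt_prediction(m, x = 0.2, tau = 1e-4)
  expect_equal(p$M1, -1000 * 0.2 * 1e-4 * (1 - 1000 * 1e-4 / 2))
  exact <- 0.2 * (exp(-1000 * 1e-4) - 1)
  expect_lt(abs(p$M1 - exact), (1000 * 1e-4)^3 * 0.2)
  ## leading order as tau -> 0
  tau0 <- 1e-12
  p0 <- finite_dt_prediction(m, x = 0.1, tau = tau0)
  expect_equal(p0$M1 / tau0, -1000 * 0.1, tolerance = 1e-6)
  expect_equal(p0$M2 / (2 * tau0), 50, tolerance = 1e-6)
  ## nonlinear model at the trap centre: Monte-Carlo oracle over tau with
  ## 20 Euler substeps per path
  mn <- langevin_model(7100, 52, 1040)
  tau <- 1e-5; nsub <- 10; h <- tau / nsub; N <- 1e5
  set.seed(77)
  xs <- numeric(N)
  for (s in seq_len(nsub))
    xs <- xs - 7100 * xs * h + sqrt(2 * (52 + 1040 * xs^2) * h) * rnorm(N)
  pn <- finite_dt_prediction(mn, x = 0, tau = tau)
  se_m2 <- sd(xs^2) / sqrt(N)
  expect_lt(abs(mean(xs^2) - pn$M2), 6 * se_m2)
  expect_lt(abs(mean(xs) - pn$M1), 4 * sd(xs) / sqrt(N))
  ## the quadratic-in-tau correction is genuinely resolved: the leading
  ## term alone misses the Monte-Carlo mean by far more than its error
  expect_gt(abs(mean(xs^2) - 2 * tau * 52), 10 * se_m2)
})

test_that("estimator preconditions are enforced", {
  ts <- time_series(rnorm(1000), dt = 1e-3)
  expect_error(conditional_moments(ts, lags = 200), "below n/10")
  far <- bin_grid(seq(100, 101, length.out = 7))
  expect_error(conditional_moments(ts, lags = 1:3, grid = far),
               "does not overlap")
  expect_error(bin_grid(c(1, 2)), "length")
  expect_error(bin_grid(c(1, 2, 2, 3, 4, 5)))
  ## bins failing min_count are excluded and reported
  km <- km_coefficients(ts, lags = 1:3,
                        grid = default_grid(ts, bins = 30, min_count = 1e5))
  expect_gt(length(attr(km, "excluded")), 0)
})
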
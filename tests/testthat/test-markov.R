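test_that("three-point histograms match a brute-force count", {
  set.seed(11)
  x <- rnorm(300)
  ts <- time_series(x, dt = 0.5)
  edges <- seq(-3, 3, length.out = 4)
  tp <- three_point_stats(ts, delta = 2, edges = edges)
  bf <- array(0, c(3, 3, 3))
  n_out <- 0
  for (i in 1:(300 - 4)) {
    b <- findInterval(c(x[i], x[i + 2], x[i + 4]), edges, rightmost.closed = TRUE)
    if (all(b >= 1 & b <= 3)) bf[b[1], b[2], b[3]] <- bf[b[1], b[2], b[3]] + 1
    else n_out <- n_out + 1
  }
  expect_identical(tp$joint3, array(as.integer(bf), dim = c(3, 3, 3)))
  expect_equal(tp$out_of_range, n_out)
  expect_equal(tp$total + n_out, 300L - 4L)
})

test_that("independent two-bin symbols give the uniform three-point density", {
  set.seed(12)
  n <- 64000
  x <- sample(c(-0.5, 0.5), n, replace = TRUE)
  tp <- three_point_stats(time_series(x, dt = 1), delta = 1,
                          edges = c(-1, 0, 1))
  p <- tp$joint3 / tp$total
  se <- sqrt(0.125 * 0.875 / tp$total)
  expect_true(all(abs(p - 1 / 8) < 5 * se))
})

test_that("a two-state chain reproduces pi_i T_ij T_jk and factorizes", {
  set.seed(13)
  T_mat <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  pi_st <- c(0.6, 0.4)                      # stationary distribution of T_mat
  n <- 2e5
  s <- integer(n); s[1] <- 1L
  u <- runif(n)
  for (i in 2:n) s[i] <- if (u[i] < T_mat[s[i - 1], 1]) 1L else 2L
  ts <- time_series(c(-0.5, 0.5)[s], dt = 1)
  tp <- three_point_stats(ts, delta = 1, edges = c(-1, 0, 1))
  p3 <- tp$joint3 / tp$total
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_lt(abs(p3[i, j, k] - pi_st[i] * T_mat[i, j] * T_mat[j, k]), 0.02)
  ## the chain is Markov: the factorization chi2 stays at the noise level
  r <- chi2_from_histograms(tp)
  expect_lt(r$chi2_nu, 2)
  expect_identical(r$N, 8L)
})

test_that("exactly factorized probabilities give chi2 = 0", {
  T_mat <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  pi_st <- c(0.6, 0.4)
  c3 <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    c3[i, j, k] <- 1e6 * pi_st[i] * T_mat[i, j] * T_mat[j, k]
  tp <- structure(list(joint3 = c3, edges = c(-1, 0, 1), delta = 1L,
                       dt = 1, total = sum(c3), out_of_range = 0L),
                  class = "ot_3pt")
  r <- chi2_from_histograms(tp)
  expect_lt(r$chi2, 1e-16)         # zero to machine precision
  expect_lt(r$chi2_nu, 1e-16)
})

test_that("marginalizing the three-point counts reproduces the two-point counts", {
  ts <- markov_ou(n = 5e4)
  tp <- three_point_stats(ts, delta = 3, bins = 6)
  ## counting identity: all lower-order histograms derive from joint3
  c12 <- apply(tp$joint3, c(1, 2), sum)
  expect_identical(sum(c12), tp$total)
  expect_identical(sum(tp$joint3), tp$total)
})

test_that("the reduced chi2 is invariant under affine rescaling", {
  ts <- markov_ou(n = 5e4)
  edges <- seq(mean(ts$values) - 3 * sd(ts$values),
               mean(ts$values) + 3 * sd(ts$values), length.out = 11)
  r1 <- chi2_markov(ts, delta = 2, edges = edges)
  a <- 37.5; cshift <- -2.2
  ts2 <- time_series(a * ts$values + cshift, dt = ts$dt)
  r2 <- chi2_markov(ts2, delta = 2, edges = a * edges + cshift)
  expect_equal(r1$chi2_nu, r2$chi2_nu, tolerance = 1e-12)
  expect_identical(r1$N, r2$N)
})

test_that("Markov records give a flat profile; filtering destroys Markovianity below its window", {
  ts <- markov_ou()
  deltas <- c(1:6, 8, 10, 15, 20)
  sc <- scan_me_timescale(ts, deltas = deltas, bins = 10)
  expect_lt(max(sc$chi2_nu), 3)            # flat, order-one everywhere
  expect_lte(attr(sc, "tau_M_samples"), 5)
  w <- 10
  scf <- scan_me_timescale(moving_average_series(ts, w), deltas = deltas,
                           bins = 10)
  ## strongly non-Markov below the filter window ...
  expect_gt(scf$chi2_nu[scf$delta_samples == 2], 20)
  expect_gt(scf$chi2_nu[scf$delta_samples == 2] /
              scf$chi2_nu[scf$delta_samples == 20], 10)
  ## ... decreasing toward the window scale, beyond which it is Markov again
  v <- scf$chi2_nu[match(c(5, 6, 8, 10), scf$delta_samples)]
  expect_true(all(diff(v) < 0))
  expect_gte(attr(scf, "tau_M_samples"), w)
  expect_equal(attr(scf, "tau_M_seconds"),
               attr(scf, "tau_M_samples") * ts$dt)
})

test_that("scan tie-breaking prefers the smallest spacing", {
  ts <- markov_ou(n = 5e4)
  sc <- scan_me_timescale(ts, deltas = c(4, 2, 9), bins = 8)
  expect_identical(sc$delta_samples, c(2L, 4L, 9L))  # sorted scan
  dup <- sc
  dup$chi2_nu <- rep(1, 3)                 # forced tie
  expect_identical(dup$delta_samples[which.min(dup$chi2_nu)], 2L)
})

test_that("degenerate grids and spacings are rejected", {
  ts <- markov_ou(n = 5e4)
  expect_error(three_point_stats(ts, delta = ts$n %/% 2), "2 \\* delta")
  expect_error(three_point_stats(ts, delta = 1, edges = c(1, 1, 2)))
  off <- three_point_stats(ts, delta = 1,
                           edges = max(ts$values) + c(1, 2, 3))
  expect_error(chi2_from_histograms(off), "no includable cells")
})
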
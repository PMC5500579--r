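#' Position-space bin grid for conditional averaging
#'
#' @param edges strictly increasing bin boundaries (at least 6, i.e. 5 bins).
#' @param min_count minimum number of increment pairs a bin must hold, at
#'   every lag, to be reported.
#' @return An object of class `ot_bingrid`.
#' @export
bin_grid <- function(edges, min_count = 100) {
  edges <- as.numeric(edges)
  stopifnot(length(edges) >= 6L, all(is.finite(edges)), all(diff(edges) > 0),
            min_count >= 1)
  structure(list(edges = edges, min_count = min_count), class = "ot_bingrid")
}

#' Default grid: equal-width bins spanning mean +/- span standard deviations
#'
#' @param ts a [time_series()].
#' @param bins number of bins (default 50).
#' @param span half-width of the grid in standard deviations (default 4).
#' @param min_count passed to [bin_grid()].
#' @return An `ot_bingrid`.
#' @export
default_grid <- function(ts, bins = 50, span = 4, min_count = 100) {
  m <- mean(ts$values); s <- sd(ts$values)
  bin_grid(seq(m - span * s, m + span * s, length.out = bins + 1L),
           min_count = min_count)
}

#' Binned conditional moments of the increments
#'
#' For each lag `l` (in samples) and bin `B`, estimates the conditional
#' moments of the increment `d = x(t + l dt) - x(t)` given `x(t) in B`,
#' each divided by the lag time `tau = l * dt`:
#' \deqn{M_k(B, \tau) = \mathrm{mean}\{d^k : x_t \in B\} / \tau, \quad k = 1, 2, 4.}
#' Standard errors are the within-bin standard deviations of `d^k` divided
#' by `sqrt(count) * tau`. All overlapping pairs along the record enter the
#' averages (conditional temporal averaging over the entire series).
#'
#' @param ts a [time_series()].
#' @param lags integer vector of lag multiples of `dt`; each must be below
#'   `n/10`.
#' @param grid an [bin_grid()]; defaults to [default_grid()] of the series.
#' @return An object of class `ot_moments`: matrices `count`, `M1`, `M2`,
#'   `M4`, `se1`, `se2`, `se4` of dimension bins x lags, plus `centers`,
#'   `edges`, `lags`, `tau`, `dt`, `min_count`, and the per-lag number of
#'   out-of-grid pairs (`out_of_range`, reported, never silently dropped).
#' @export
conditional_moments <- function(ts, lags = 1:5, grid = NULL) {
  stopifnot(inherits(ts, "ot_timeseries"))
  lags <- sort(unique(as.integer(lags)))
  stopifnot(length(lags) >= 1L, all(lags >= 1L))
  if (max(lags) >= ts$n / 10)
    stop("maximum lag must be below n/10")
  if (is.null(grid)) grid <- default_grid(ts)
  stopifnot(inherits(grid, "ot_bingrid"))
  edges <- grid$edges
  nb <- length(edges) - 1L
  x <- ts$values
  rng <- range(x)
  if (rng[2] <= edges[1] || rng[1] >= edges[nb + 1L])
    stop(sprintf("grid [%g, %g] does not overlap the data range [%g, %g]",
                 edges[1], edges[nb + 1L], rng[1], rng[2]))
  nl <- length(lags)
  dims <- c(nb, nl)
  count <- array(0, dims)
  M <- list(array(NA_real_, dims), array(NA_real_, dims), array(NA_real_, dims))
  SE <- list(array(NA_real_, dims), array(NA_real_, dims), array(NA_real_, dims))
  oor <- integer(nl)
  for (j in seq_len(nl)) {
    l <- lags[j]
    m <- ts$n - l
    x0 <- x[seq_len(m)]
    d <- x[(l + 1L):ts$n] - x0
    idx <- findInterval(x0, edges, rightmost.closed = TRUE)
    keep <- idx >= 1L & idx <= nb
    oor[j] <- m - sum(keep)
    idx <- idx[keep]; d <- d[keep]
    tau <- l * ts$dt
    sums <- rowsum(cbind(d, d^2, d^4, d^8), idx)
    occupied <- as.integer(rownames(sums))
    cnt <- tabulate(idx, nbins = nb)
    count[, j] <- cnt
    c_occ <- cnt[occupied]
    for (k in seq_along(c(1L, 2L, 4L))) {
      p <- c(1L, 2L, 4L)[k]
      mean_k <- sums[, k] / c_occ
      mean_2k <- sums[, min(k + 1L, 4L)] / c_occ     # k=1->d^2, k=2->d^4, k=3(d^4)->d^8
      var_k <- pmax(mean_2k - mean_k^2, 0)
      M[[k]][occupied, j] <- mean_k / tau
      SE[[k]][occupied, j] <- sqrt(var_k / c_occ) / tau
    }
  }
  structure(list(count = count, M1 = M[[1]], M2 = M[[2]], M4 = M[[3]],
                 se1 = SE[[1]], se2 = SE[[2]], se4 = SE[[3]],
                 centers = (edges[-1] + edges[-(nb + 1L)]) / 2,
                 edges = edges, lags = lags, tau = lags * ts$dt, dt = ts$dt,
                 min_count = grid$min_count, out_of_range = oor,
                 n = ts$n),
            class = "ot_moments")
}

#' @export
print.ot_moments <- function(x, ...) {
  cat(sprintf("Conditional moments: %d bins x %d lags (tau = %s)\n",
              length(x$centers), length(x$lags),
              paste(signif(x$tau, 3), collapse = ", ")))
  cat(sprintf("  pairs out of grid per lag: %s\n",
              paste(x$out_of_range, collapse = ", ")))
  invisible(x)
}

## weighted straight-line fit y ~ tau returning intercept, slope and their SEs;
## falls back to unweighted when weights are degenerate
.line_fit <- function(tau, y, w) {
  ok <- is.finite(y) & is.finite(w) & w > 0
  if (sum(ok) < 3L || !all(ok)) w <- rep(1, length(y))
  fit <- lm(y ~ tau, weights = w)
  s <- summary(fit)$coefficients
  list(intercept = s[1, 1], se_intercept = s[1, 2],
       slope = s[2, 1], se_slope = s[2, 2],
       residual = sqrt(mean(fit$residuals^2)))
}

#' Zero-lag extrapolation of the scaled conditional moments
#'
#' Per bin, fits `M_k(tau)` (already divided by `tau`) against `tau` with a
#' straight line and returns the `tau = 0` intercept. The finite-sampling
#' correction to the scaled moments is linear in `tau` to leading order, so
#' the intercept removes the O(tau) estimator bias.
#'
#' @param cm an [conditional_moments()] result with at least 3 lags.
#' @param k moment order: 1, 2 or 4.
#' @param method `"weighted-linear"` (weights `1/SE^2`) or `"linear"`.
#' @return A data frame with one row per bin: `center`, `included` (bin met
#'   `min_count` at every lag), `intercept`, `se`, `slope`, `residual`.
#' @export
extrapolate_zero_lag <- function(cm, k = 2, method = c("weighted-linear", "linear")) {
  stopifnot(inherits(cm, "ot_moments"), k %in% c(1, 2, 4))
  method <- match.arg(method)
  if (length(cm$lags) < 3L)
    stop("zero-lag extrapolation needs at least 3 lags")
  Mk <- cm[[paste0("M", k)]]
  SEk <- cm[[c("1" = "se1", "2" = "se2", "4" = "se4")[as.character(k)]]]
  nb <- length(cm$centers)
  included <- apply(cm$count >= cm$min_count, 1L, all)
  out <- data.frame(center = cm$centers, included = included,
                    intercept = NA_real_, se = NA_real_,
                    slope = NA_real_, residual = NA_real_)
  for (i in which(included)) {
    w <- if (method == "weighted-linear") 1 / SEk[i, ]^2 else rep(1, length(cm$tau))
    f <- .line_fit(cm$tau, Mk[i, ], w)
    out$intercept[i] <- f$intercept
    out$se[i] <- f$se_intercept
    out$slope[i] <- f$slope
    out$residual[i] <- f$residual
  }
  out
}

#' Kramers-Moyal coefficients from a time series
#'
#' Estimates the drift `D1(x)`, diffusion `D2(x)` and fourth-order
#' coefficient `D4(x)` as the zero-lag limits of the scaled conditional
#' moments: `D1 = M1`, `D2 = M2 / 2`, `D4 = M4 / 24` at `tau -> 0`. With
#' `extrapolate = TRUE` (default) the limit is taken per bin by linear
#' extrapolation over the supplied lags; with `extrapolate = FALSE` the
#' smallest lag is used directly, which carries an O(tau) bias (for a
#' harmonic trap it manifests as a spurious quadratic term
#' `~(1 - e^{-Q tau})^2 / (2 tau) x^2` in `D2`).
#'
#' @inheritParams conditional_moments
#' @param extrapolate take the zero-lag limit (TRUE) or use the smallest
#'   lag directly (FALSE).
#' @return An object of class `ot_km`: data frame with `center`, `count`
#'   (at the smallest lag), `D1`, `se_D1`, `D2`, `se_D2`, `D4`, `se_D4`
#'   for the bins meeting `min_count` at every lag, plus attributes
#'   `diagnostics` (per-bin extrapolation slopes and residuals),
#'   `excluded` (bin centers dropped by the count threshold), `lags`,
#'   `dt`, `extrapolated`, `variance` (sample variance of the series).
#' @export
km_coefficients <- function(ts, lags = 1:5, grid = NULL, extrapolate = TRUE) {
  cm <- conditional_moments(ts, lags = lags, grid = grid)
  if (extrapolate) {
    e1 <- extrapolate_zero_lag(cm, 1)
    e2 <- extrapolate_zero_lag(cm, 2)
    e4 <- extrapolate_zero_lag(cm, 4)
    included <- e1$included
    D1 <- e1$intercept; s1 <- e1$se
    D2 <- e2$intercept / 2; s2 <- e2$se / 2
    D4 <- e4$intercept / 24; s4 <- e4$se / 24
    diag <- data.frame(center = cm$centers,
                       slope_M1 = e1$slope, residual_M1 = e1$residual,
                       slope_M2 = e2$slope, residual_M2 = e2$residual)
  } else {
    included <- apply(cm$count >= cm$min_count, 1L, all)
    D1 <- cm$M1[, 1]; s1 <- cm$se1[, 1]
    D2 <- cm$M2[, 1] / 2; s2 <- cm$se2[, 1] / 2
    D4 <- cm$M4[, 1] / 24; s4 <- cm$se4[, 1] / 24
    diag <- data.frame(center = cm$centers)
  }
  out <- data.frame(center = cm$centers, count = cm$count[, 1],
                    D1 = D1, se_D1 = s1, D2 = D2, se_D2 = s2,
                    D4 = D4, se_D4 = s4)[included, ]
  if (nrow(out) && any(out$D2 <= 0, na.rm = TRUE))
    warning("non-positive D2 in some reported bins; inspect lags/binning")
  structure(out, class = c("ot_km", "data.frame"),
            diagnostics = diag, excluded = cm$centers[!included],
            lags = cm$lags, dt = cm$dt, extrapolated = extrapolate,
            variance = var(ts$values), moments = cm)
}

#' Pawula truncation diagnostic
#'
#' Median over bins of `|D4| / D2`. When the ratio is small the
#' Kramers-Moyal expansion truncates to a Fokker-Planck equation and the
#' reconstructed dynamics is a diffusion. The conventional check is made on
#' the series standardized to unit variance; since `D4/D2` scales as the
#' variance, pass `variance` to obtain the normalized ratio without
#' re-estimating.
#'
#' @param km an [km_coefficients()] result.
#' @param variance if non-NULL, divides the ratio by it, yielding the value
#'   for the variance-standardized series.
#' @return Scalar median ratio.
#' @export
pawula_ratio <- function(km, variance = NULL) {
  stopifnot(inherits(km, "ot_km"))
  ok <- is.finite(km$D4) & is.finite(km$D2) & km$D2 > 0
  if (!any(ok)) stop("no bins with positive D2")
  r <- median(abs(km$D4[ok]) / km$D2[ok])
  if (!is.null(variance)) r <- r / variance
  r
}

#' Fit the linear drift law D1(x) = -Q x
#'
#' Weighted least squares of the binned drift estimates against the bin
#' centers (weights `1/SE^2`); the trap force constant over drag is the
#' negated slope.
#'
#' @param km an [km_coefficients()] result with at least 5 bins.
#' @return An object of class `ot_driftfit`: `Q_hat`, `se_Q`, `intercept`,
#'   `se_intercept`, `r_squared`.
#' @export
fit_drift <- function(km) {
  stopifnot(inherits(km, "ot_km"))
  d <- km[is.finite(km$D1) & is.finite(km$se_D1) & km$se_D1 > 0, ]
  if (nrow(d) < 5L) stop("drift fit needs at least 5 usable bins")
  if (length(unique(d$center)) < 2L) stop("singular drift fit: bins coincide")
  fit <- lm(D1 ~ center, data = d, weights = 1 / se_D1^2)
  s <- summary(fit)$coefficients
  Q_hat <- -s[2, 1]
  if (Q_hat <= 0) warning("non-positive drift slope: data are not trap-like")
  structure(list(Q_hat = Q_hat, se_Q = s[2, 2],
                 intercept = s[1, 1], se_intercept = s[1, 2],
                 r_squared = summary(fit)$r.squared, n_bins = nrow(d)),
            class = "ot_driftfit")
}

#' @export
print.ot_driftfit <- function(x, ...) {
  cat(sprintf("Drift fit D1(x) = -Q x: Q = %.4g +/- %.2g (%d bins, R^2 = %.4f)\n",
              x$Q_hat, x$se_Q, x$n_bins, x$r_squared))
  invisible(x)
}

#' Fit the quadratic diffusion law D2(x) = a + b x^2
#'
#' Weighted least squares of the binned diffusion estimates against the
#' squared bin centers. Also reports the count-weighted average of `D2(x)`
#' over bins, the quantity the constant-diffusion power-spectrum estimate
#' gravitates towards.
#'
#' @param km an [km_coefficients()] result with at least 5 bins.
#' @return An object of class `ot_difffit`: `a_hat`, `se_a`, `b_hat`,
#'   `se_b`, `d2_average`, `r_squared`.
#' @export
fit_diffusion <- function(km) {
  stopifnot(inherits(km, "ot_km"))
  d <- km[is.finite(km$D2) & is.finite(km$se_D2) & km$se_D2 > 0, ]
  if (nrow(d) < 5L) stop("diffusion fit needs at least 5 usable bins")
  d$x2 <- d$center^2
  if (length(unique(d$x2)) < 2L) stop("singular diffusion fit")
  fit <- lm(D2 ~ x2, data = d, weights = 1 / se_D2^2)
  s <- summary(fit)$coefficients
  if (s[1, 1] <= 0) warning("non-positive diffusion intercept a_hat")
  structure(list(a_hat = s[1, 1], se_a = s[1, 2],
                 b_hat = s[2, 1], se_b = s[2, 2],
                 d2_average = weighted.mean(d$D2, d$count),
                 r_squared = summary(fit)$r.squared, n_bins = nrow(d)),
            class = "ot_difffit")
}

#' @export
print.ot_difffit <- function(x, ...) {
  cat(sprintf("Diffusion fit D2(x) = a + b x^2: a = %.4g +/- %.2g, b = %.4g +/- %.2g\n",
              x$a_hat, x$se_a, x$b_hat, x$se_b))
  cat(sprintf("  count-weighted average D2: %.4g (%d bins)\n", x$d2_average, x$n_bins))
  invisible(x)
}

#' Finite-sampling-interval prediction for the conditional moments
#'
#' Evaluates the second-order short-time expansion of the first two
#' conditional moments for the parametric trap model (drift `-Qx`,
#' diffusion `D0 + b x^2`):
#' \deqn{M^{(1)} \approx \Delta t D^{(1)} + \tfrac{\Delta t^2}{2}
#'   [D^{(1)} (D^{(1)})' + D^{(2)} (D^{(1)})''],}
#' \deqn{M^{(2)} \approx 2 \Delta t D^{(2)} + \Delta t^2 [(D^{(1)})^2
#'   + 2 D^{(2)} (D^{(1)})' + D^{(1)} (D^{(2)})' + D^{(2)} (D^{(2)})''].}
#' Used to quantify the estimator bias at finite lag and to validate the
#' zero-lag extrapolation.
#'
#' @param model a [langevin_model()].
#' @param x position(s) at which to evaluate.
#' @param tau lag time.
#' @return A list with `M1` and `M2` (unscaled moments, not divided by tau).
#' @export
finite_dt_prediction <- function(model, x, tau) {
  stopifnot(inherits(model, "langevin_model"), tau >= 0)
  Q <- model$Q; D0 <- model$D0; b <- model$b
  D1 <- -Q * x
  D2 <- D0 + b * x^2
  ## (D1)' = -Q, (D1)'' = 0, (D2)' = 2 b x, (D2)'' = 2 b
  M1 <- tau * D1 + tau^2 / 2 * (D1 * (-Q))
  M2 <- 2 * tau * D2 + tau^2 * (D1^2 + 2 * D2 * (-Q) + D1 * (2 * b * x) + D2 * (2 * b))
  list(M1 = M1, M2 = M2)
}
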
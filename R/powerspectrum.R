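#' Blocked periodogram of a position record
#'
#' Splits the record into `n_blocks` non-overlapping segments, removes each
#' segment's mean, and averages the per-segment two-sided periodograms
#' \eqn{p(f) = |x(f)|^2 / L} (discrete form `|DFT|^2 dt / m` for a segment
#' of `m` samples). Averaging reduces the periodogram's exponential scatter
#' to a relative standard deviation of `1/sqrt(n_blocks)`, which is what
#' the Lorentzian fit weights assume. The normalization is such that the
#' two-sided sum `2 * sum(p) * df` equals the series variance (Parseval).
#'
#' @param ts a [time_series()].
#' @param n_blocks number of segments (default 20); `n >= 2 * n_blocks`.
#' @return An object of class `ot_psd`: `f` (positive frequencies, Hz or
#'   1/sim-time), `p` (two-sided spectral density), `df`, `n_blocks`,
#'   `block_length` (time), `L_total`, `dt`, `variance` of the record.
#' @export
periodogram <- function(ts, n_blocks = 20) {
  stopifnot(inherits(ts, "ot_timeseries"),
            is.numeric(n_blocks), length(n_blocks) == 1L, n_blocks >= 1)
  if (n_blocks > ts$n / 2) stop("n_blocks must be <= n/2")
  m <- ts$n %/% n_blocks
  kmax <- (m - 1L) %/% 2L           # positive frequencies below Nyquist
  if (kmax < 1L) stop("blocks too short for any positive frequency")
  acc <- numeric(kmax)
  for (bl in seq_len(n_blocks)) {
    seg <- ts$values[((bl - 1L) * m + 1L):(bl * m)]
    X <- fft(seg - mean(seg))
    acc <- acc + (Mod(X[2:(kmax + 1L)])^2) * ts$dt / m
  }
  structure(list(f = (1:kmax) / (m * ts$dt), p = acc / n_blocks,
                 df = 1 / (m * ts$dt), n_blocks = n_blocks,
                 block_length = m * ts$dt, L_total = ts$n * ts$dt,
                 dt = ts$dt, variance = var(ts$values)),
            class = "ot_psd")
}

#' @export
print.ot_psd <- function(x, ...) {
  cat(sprintf("Blocked periodogram: %d frequencies in [%.4g, %.4g], %d blocks of %g\n",
              length(x$f), min(x$f), max(x$f), x$n_blocks, x$block_length))
  invisible(x)
}

#' @export
as.data.frame.ot_psd <- function(x, ...) data.frame(f = x$f, p = x$p)

#' Two-sided Lorentzian spectral density of a harmonic trap
#'
#' `D / (2 pi^2 (f^2 + f_c^2))`; integrates over all frequencies to the
#' trap variance `D * (2 pi f_c)^{-1} * ...` = `D/Q` with `Q = 2 pi f_c`.
#'
#' @param f frequency (vectorized).
#' @param f_c corner frequency.
#' @param D diffusion coefficient (input-unit^2 per time).
#' @return Spectral density values.
#' @export
lorentzian_psd <- function(f, f_c, D) D / (2 * pi^2 * (f^2 + f_c^2))

## closed-form minimizer of sum((p * (a + b f^2) - 1)^2): the ratio-space
## linear fit used to initialize the iterated WLS
.lorentz_init <- function(f, p) {
  X <- cbind(p, p * f^2)
  qr.solve(X, rep(1, length(p)))
}

#' Fit a Lorentzian to a blocked periodogram
#'
#' Fits `p(f) = D / (2 pi^2 (f^2 + f_c^2))` by weighted least squares with
#' weights `n_blocks / p_model^2` (the block-averaged periodogram has
#' relative standard deviation `1/sqrt(n_blocks)`), iterating the weights
#' to convergence so the estimating equations are unbiased. The fit is
#' initialized with the closed-form ratio regression of `1` on
#' `(p, p f^2)`. Parameter standard errors come from the Gauss-Newton
#' covariance at the optimum.
#'
#' @param ps an [periodogram()] result.
#' @param f_range numeric length-2 fit window; default
#'   `c(3 / L_total, Nyquist / 4)`. The upper quarter-Nyquist cap keeps the
#'   discrete-sampling (aliasing) distortion of the spectrum below the
#'   percent level. At least 10 points must fall in the window.
#' @param max_iter maximum weight-update iterations.
#' @return An object of class `ot_lorfit`: `f_c`, `se_fc`, `D`, `se_D`,
#'   `f_range`, `n_points`, `n_blocks`, `gof` (reduced chi-squared of the
#'   weighted residuals), `iterations`, `converged`.
#' @export
fit_lorentzian <- function(ps, f_range = NULL, max_iter = 50) {
  stopifnot(inherits(ps, "ot_psd"))
  nyquist <- 1 / (2 * ps$dt)
  if (is.null(f_range)) f_range <- c(3 / ps$L_total, nyquist / 4)
  stopifnot(length(f_range) == 2L, f_range[1] < f_range[2])
  sel <- ps$f >= f_range[1] & ps$f <= f_range[2]
  if (sum(sel) < 10L) stop("need at least 10 spectral points in the fit range")
  f <- ps$f[sel]; p <- ps$p[sel]
  cf <- .lorentz_init(f, p)
  clamped <- FALSE
  if (any(cf <= 0)) {              # pathological input: clamp and flag
    cf <- pmax(cf, 1e-12 * max(abs(cf)))
    clamped <- TRUE
    warning("negative parameter excursion in the initial fit; clamped")
  }
  ## Model in inverse space: 1/p_model = g = a + b f^2. The converged
  ## model-weighted WLS satisfies sum((p - 1/g) [1, f^2]) = 0, i.e.
  ## sum((p g - 1) / g [1, f^2]) = 0; solve by relaxation: fix the 1/g
  ## factor at the previous iterate, which leaves a 2x2 linear system.
  f2 <- f^2
  a <- cf[1]; b <- cf[2]
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    gp <- a + b * f2
    pg <- p / gp
    M <- matrix(c(sum(pg), sum(pg * f2), sum(pg * f2), sum(pg * f2^2)), 2, 2)
    v <- c(sum(1 / gp), sum(f2 / gp))
    ab_new <- tryCatch(solve(M, v), error = function(e) c(NA_real_, NA_real_))
    if (any(!is.finite(ab_new)) || any(ab_new <= 0)) {
      ab_new <- pmax(abs(ab_new), 1e-12 * c(a, b))
      clamped <- TRUE
    }
    delta <- max(abs(ab_new - c(a, b)) / pmax(abs(c(a, b)), 1e-300))
    a <- ab_new[1]; b <- ab_new[2]
    if (delta < 1e-10) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("Lorentzian fit did not converge after ", max_iter,
         " weight iterations (last f_c = ", signif(sqrt(a / b), 6),
         ", D = ", signif(2 * pi^2 / b, 6), ")")
  ## Gauss-Newton covariance in (a, b) with weights 1/model^2
  g <- a + b * f2
  J <- cbind(1 / g^2, f2 / g^2) * g        # d(model)/d(a,b) * weight (1/model)
  r <- (p - 1 / g) * g
  dof <- length(f) - 2L
  s2 <- sum(r^2) / dof
  XtX <- crossprod(J)
  cov_ab <- tryCatch(solve(XtX) * s2, error = function(e) matrix(NA_real_, 2, 2))
  f_c <- sqrt(a / b)
  D <- 2 * pi^2 / b
  grad_fc <- c(1 / (2 * sqrt(a * b)), -sqrt(a) / (2 * b^1.5))
  se_fc <- sqrt(drop(t(grad_fc) %*% cov_ab %*% grad_fc))
  se_D <- 2 * pi^2 / b^2 * sqrt(cov_ab[2, 2])
  if (!is.finite(D) || D <= 0 || !is.finite(f_c))
    stop("Lorentzian fit returned non-positive parameters")
  structure(list(f_c = f_c, se_fc = se_fc, D = D, se_D = se_D,
                 f_range = f_range, n_points = length(f),
                 n_blocks = ps$n_blocks,
                 gof = s2 * ps$n_blocks,    # ~1 when residuals are pure sampling noise
                 iterations = iterations, converged = converged,
                 clamped = clamped),
            class = "ot_lorfit")
}

#' @export
print.ot_lorfit <- function(x, ...) {
  cat(sprintf("Lorentzian fit: f_c = %.6g +/- %.2g, D = %.6g +/- %.2g\n",
              x$f_c, x$se_fc, x$D, x$se_D))
  cat(sprintf("  range [%.4g, %.4g], %d points, %d blocks, reduced chi2 = %.3g\n",
              x$f_range[1], x$f_range[2], x$n_points, x$n_blocks, x$gof))
  invisible(x)
}

#' Physical context of the trapping experiment
#'
#' Bead radius, fluid viscosity and temperature; everything needed for the
#' Stokes drag and the Einstein diffusion coefficient.
#'
#' @param radius bead radius, metres.
#' @param viscosity dynamic viscosity, Pa s.
#' @param temperature absolute temperature, K.
#' @return An object of class `ot_physical` (includes `k_B`).
#' @export
physical_context <- function(radius, viscosity, temperature) {
  stopifnot(radius > 0, viscosity > 0, temperature > 0)
  structure(list(radius = radius, viscosity = viscosity,
                 temperature = temperature, k_B = .kB),
            class = "ot_physical")
}

#' Stokes drag coefficient
#'
#' `gamma = 6 pi eta a` for a sphere of radius `a` in a fluid of dynamic
#' viscosity `eta`.
#'
#' @param ctx an [physical_context()].
#' @return Drag coefficient, kg/s.
#' @export
drag_coefficient <- function(ctx) {
  stopifnot(inherits(ctx, "ot_physical"))
  6 * pi * ctx$viscosity * ctx$radius
}

#' Einstein diffusion coefficient `k_B T / gamma`
#'
#' @param ctx an [physical_context()].
#' @return Diffusion coefficient in m^2/s.
#' @export
einstein_diffusion <- function(ctx) {
  ctx$k_B * ctx$temperature / drag_coefficient(ctx)
}

#' Trap stiffness from the corner frequency
#'
#' `k = 2 pi gamma f_c`.
#'
#' @param f_c corner frequency, Hz.
#' @param gamma drag coefficient, kg/s.
#' @return Stiffness, N/m.
#' @export
stiffness_from_fc <- function(f_c, gamma) {
  stopifnot(f_c >= 0, gamma >= 0)
  2 * pi * gamma * f_c
}

#' Volt-to-metre conversion factor
#'
#' `beta = sqrt(D_SI / D_V)`: the detector calibration factor relating the
#' voltage signal to metres, from the physical (Einstein) diffusion
#' coefficient and the diffusion coefficient fitted in volt units.
#'
#' @param D_SI diffusion coefficient in m^2/s.
#' @param D_V diffusion coefficient in volt^2/s.
#' @return Conversion factor, m/volt.
#' @export
conversion_factor <- function(D_SI, D_V) {
  if (!is.finite(D_SI) || D_SI <= 0) stop("D_SI must be positive")
  if (!is.finite(D_V) || D_V <= 0) stop("D_V must be positive")
  sqrt(D_SI / D_V)
}
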
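#' Langevin trap model with linear drift and quadratic diffusion
#'
#' Parameterizes the overdamped Ito Langevin equation
#' \deqn{dx = -Q x\, dt + \sqrt{2 (D_0 + b x^2)}\, dW}
#' used both to generate synthetic bead trajectories and as the reference
#' model the estimators are validated against. `Q` is the force constant
#' over the drag (stiffness/drag ratio, 1/time), `D0` the diffusion
#' coefficient at the trap centre (length^2/time), and `b` the quadratic
#' coefficient of the position-dependent diffusion (1/time). In the linear
#' theory of a Hookean trap, `Q = k/gamma` and `D0 = kB*T/gamma`.
#'
#' A finite stationary variance requires `Q > b`; the stationary density is
#' proportional to \eqn{(D_0 + b x^2)^{-(1 + Q/2b)}} and its variance is
#' `D0 / (Q - b)`.
#'
#' @param Q force constant over drag, must be > 0.
#' @param D0 base diffusion coefficient, must be > 0.
#' @param b quadratic diffusion coefficient, must be >= 0.
#' @return An object of class `langevin_model`.
#' @examples
#' m <- langevin_model(Q = 1000, D0 = 50)
#' stationary_variance(m)   # 0.05
#' @export
langevin_model <- function(Q, D0, b = 0) {
  stopifnot(is.numeric(Q), length(Q) == 1L, is.finite(Q),
            is.numeric(D0), length(D0) == 1L, is.finite(D0),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (Q <= 0) stop("Q must be > 0 (stable trap)")
  if (D0 < 0) stop("D0 must be >= 0")
  if (b < 0) stop("b must be >= 0")
  if (b > 0 && Q <= b)
    warning("Q <= b: stationary variance is infinite; trajectories will blow up")
  structure(list(Q = Q, D0 = D0, b = b), class = "langevin_model")
}

#' @export
print.langevin_model <- function(x, ...) {
  cat(sprintf("Langevin model: D1(x) = -%g x, D2(x) = %g", x$Q, x$D0))
  if (x$b > 0) cat(sprintf(" + %g x^2", x$b))
  cat("\n")
  if (x$Q > x$b)
    cat(sprintf("  stationary variance: %g\n", x$D0 / (x$Q - x$b)))
  invisible(x)
}

#' Stationary variance of the trap model
#'
#' Closed form `D0 / (Q - b)`, obtained from the stationary solution of the
#' Fokker-Planck equation; reduces to the Ornstein-Uhlenbeck value `D0/Q`
#' when `b = 0`.
#'
#' @param model a [langevin_model()].
#' @return The stationary variance (scalar).
#' @export
stationary_variance <- function(model) {
  stopifnot(inherits(model, "langevin_model"))
  if (model$Q <= model$b)
    stop("stationary variance undefined: requires Q > b")
  model$D0 / (model$Q - model$b)
}

#' Exact Ornstein-Uhlenbeck transition moments
#'
#' For the linear model (`b = 0`) the transition density over a lag `tau` is
#' Gaussian with mean `x * exp(-Q tau)` and variance
#' `(D0/Q) (1 - exp(-2 Q tau))`. Returns the conditional mean increment and
#' conditional variance; these are the closed-form oracles for the binned
#' conditional-moment estimators.
#'
#' @param model a [langevin_model()] with `b = 0`.
#' @param x conditioning position (vectorized).
#' @param tau lag time, >= 0.
#' @return A list with `mean_increment` = E\[x(t+tau) - x | x\] and
#'   `variance` = Var\[x(t+tau) | x\].
#' @export
ou_conditional_moments <- function(model, x, tau) {
  stopifnot(inherits(model, "langevin_model"), tau >= 0)
  if (model$b != 0)
    stop("exact transition moments are available only for b = 0")
  list(mean_increment = x * (exp(-model$Q * tau) - 1),
       variance = (model$D0 / model$Q) * (1 - exp(-2 * model$Q * tau)))
}

#' Simulate a trapped-bead trajectory by Euler-Maruyama integration
#'
#' Integrates the Ito Langevin equation of [langevin_model()] with the
#' explicit Euler-Maruyama update
#' \deqn{x_{i+1} = x_i - Q x_i \Delta t + \sqrt{2 (D_0 + b x_i^2)\Delta t}\,\xi_i,}
#' with i.i.d. standard-normal \eqn{\xi_i} drawn from a counter-based
#' generator keyed by `seed` (no dependence on R's global RNG state;
#' identical seeds give bit-identical trajectories). The diffusion is
#' evaluated at the pre-increment state (Ito convention).
#'
#' The first `burn_in` steps are discarded so that the returned record is
#' stationary; the default of `ceiling(10 / (Q * dt))` steps corresponds to
#' ten trap relaxation times. With `burn_in = 0` the first returned sample
#' is `x0`.
#'
#' @param model a [langevin_model()].
#' @param n number of samples to return.
#' @param dt integration and sampling time step. A warning is emitted when
#'   `Q * dt > 0.01`, where the Euler discretization bias on the drift
#'   (~`Q*dt/2`) exceeds half a percent.
#' @param x0 initial position (default 0, the trap centre).
#' @param seed integer seed; required, recorded in the returned metadata.
#' @param burn_in number of initial steps to discard.
#' @return A [time_series()] with unit `"sim-unit"` and provenance metadata
#'   (`seed`, `model`, `burn_in`, `x0`).
#' @examples
#' ts <- simulate_langevin(langevin_model(1000, 50), n = 1e4, dt = 1e-6, seed = 1)
#' var(ts$values)   # ~ 0.05 for long records
#' @export
simulate_langevin <- function(model, n, dt, x0 = 0, seed, burn_in = NULL) {
  stopifnot(inherits(model, "langevin_model"),
            is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(x0), length(x0) == 1L, is.finite(x0))
  if (missing(seed))
    stop("an explicit integer seed is required (no implicit global RNG state)")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  if (is.null(burn_in)) burn_in <- ceiling(10 / (model$Q * dt))
  stopifnot(is.numeric(burn_in), length(burn_in) == 1L, burn_in >= 0)
  if (model$Q * dt > 0.01)
    warning(sprintf("Q * dt = %.3g > 0.01: Euler discretization bias on the drift is ~Q*dt/2",
                    model$Q * dt))
  values <- em_simulate_cpp(model$Q, model$D0, model$b,
                            n, dt, x0, seed, burn_in)
  time_series(values, dt = dt, unit = "sim-unit",
              meta = list(seed = as.integer(seed), burn_in = burn_in, x0 = x0,
                          model = unclass(model)))
}
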
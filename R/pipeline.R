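#' Calibration configuration
#'
#' Bundles every setting of the end-to-end calibration: sampling, unit,
#' physical context, Kramers-Moyal estimator settings, Markov-scan
#' settings, power-spectrum settings and the ensemble policy. The object
#' round-trips through JSON (see [write_report()]).
#'
#' @param dt sampling interval; may be NULL when the input series carries
#'   its own.
#' @param unit expected unit of the input series.
#' @param physical an [physical_context()] or NULL (simulation units: the
#'   report then compares `Q` and `D` instead of stiffness and beta).
#' @param km list: `lags` (lag multiples for the zero-lag extrapolation),
#'   `bins`, `span`, `min_count`, `extrapolate`.
#' @param markov list: `deltas` (spacings to scan), `bins`, `span`; set to
#'   NULL to skip the Markov diagnostic.
#' @param ps list: `n_blocks`, `f_range` (NULL for the default window).
#' @param ensemble list: `n_records`, `average` (only
#'   `"inverse-variance"`).
#' @return An object of class `ot_config`.
#' @export
calibration_config <- function(dt = NULL, unit = "sim-unit", physical = NULL,
                               km = list(), markov = list(), ps = list(),
                               ensemble = list()) {
  km <- utils::modifyList(list(lags = 1:5, bins = 50, span = 4,
                               min_count = 100, extrapolate = TRUE), km)
  if (!is.null(markov))
    markov <- utils::modifyList(list(deltas = 1:10, bins = 12, span = 3), markov)
  ps <- utils::modifyList(list(n_blocks = 20, f_range = NULL), ps)
  ensemble <- utils::modifyList(list(n_records = 1L, average = "inverse-variance"),
                                ensemble)
  if (!is.null(physical)) stopifnot(inherits(physical, "ot_physical"))
  stopifnot(is.null(dt) || (is.numeric(dt) && dt > 0),
            all(km$lags >= 1), km$bins >= 5, km$min_count >= 1,
            ps$n_blocks >= 1, ensemble$n_records >= 1)
  structure(list(dt = dt, unit = unit, physical = physical, km = km,
                 markov = markov, ps = ps, ensemble = ensemble),
            class = "ot_config")
}

#' Relative difference in percent, power-spectrum value as reference
#'
#' `|ps - km| / ps * 100`: the convention of the side-by-side comparison
#' table (verified against its printed rows).
#'
#' @param ps_value,km_value the two branch estimates.
#' @return Percent relative difference.
#' @export
rel_dif <- function(ps_value, km_value) abs(ps_value - km_value) / ps_value * 100

#' End-to-end calibration of a position time series
#'
#' Runs the three analysis branches on one record:
#' * the Markov-Einstein scan (diagnostic; [scan_me_timescale()]),
#' * the Kramers-Moyal branch ([km_coefficients()], [fit_drift()],
#'   [fit_diffusion()], [pawula_ratio()]),
#' * the power-spectrum branch ([periodogram()], [fit_lorentzian()]),
#'
#' and assembles a side-by-side report. With a physical context and a
#' voltage record the report carries, per branch, the stiffness
#' (`k_PS = 2 pi gamma f_c`, `k_KM = gamma * Q_hat`), the voltage diffusion
#' coefficient (`D_V_PS` = Lorentzian `D`, `D_V_KM` = quadratic-fit
#' intercept `a_hat`) and the conversion factor
#' `beta = sqrt((k_B T / gamma) / D_V)`, plus percent relative differences
#' ([rel_dif()]). Without a physical context the comparison is between the
#' force constants `Q_PS = 2 pi f_c` vs `Q_hat` and the diffusion
#' coefficients. A branch failure is caught and flagged; the report is
#' still emitted.
#'
#' @param ts a [time_series()].
#' @param config an [calibration_config()].
#' @return An object of class `ot_report`.
#' @export
calibrate <- function(ts, config = calibration_config()) {
  stopifnot(inherits(ts, "ot_timeseries"), inherits(config, "ot_config"))
  if (!is.null(config$dt) && abs(config$dt - ts$dt) > 1e-9 * ts$dt)
    stop("config dt conflicts with the series dt")
  errors <- list()
  markov <- NULL
  if (!is.null(config$markov)) {
    markov <- tryCatch(
      scan_me_timescale(ts, deltas = config$markov$deltas,
                        bins = config$markov$bins, span = config$markov$span),
      error = function(e) { errors$markov <<- conditionMessage(e); NULL })
  }
  km_branch <- tryCatch({
    grid <- default_grid(ts, bins = config$km$bins, span = config$km$span,
                         min_count = config$km$min_count)
    km <- km_coefficients(ts, lags = config$km$lags, grid = grid,
                          extrapolate = config$km$extrapolate)
    list(km = km, drift = fit_drift(km), diffusion = fit_diffusion(km),
         pawula = pawula_ratio(km, variance = attr(km, "variance")))
  }, error = function(e) { errors$km <<- conditionMessage(e); NULL })
  ps_branch <- tryCatch({
    psd <- periodogram(ts, n_blocks = config$ps$n_blocks)
    list(psd = psd, fit = fit_lorentzian(psd, f_range = config$ps$f_range))
  }, error = function(e) { errors$ps <<- conditionMessage(e); NULL })

  est <- list()
  if (!is.null(ps_branch)) {
    est$Q_PS <- 2 * pi * ps_branch$fit$f_c
    est$se_Q_PS <- 2 * pi * ps_branch$fit$se_fc
    est$D_V_PS <- ps_branch$fit$D
    est$se_D_V_PS <- ps_branch$fit$se_D
  }
  if (!is.null(km_branch)) {
    est$Q_KM <- km_branch$drift$Q_hat
    est$se_Q_KM <- km_branch$drift$se_Q
    est$D_V_KM <- km_branch$diffusion$a_hat
    est$se_D_V_KM <- km_branch$diffusion$se_a
    est$b_KM <- km_branch$diffusion$b_hat
    est$se_b_KM <- km_branch$diffusion$se_b
    est$D_V_KM_avg <- km_branch$diffusion$d2_average
  }
  if (!is.null(config$physical) && !is.null(est$Q_PS) && !is.null(est$Q_KM)) {
    gamma <- drag_coefficient(config$physical)
    D_SI <- einstein_diffusion(config$physical)
    est$gamma <- gamma
    est$k_PS <- gamma * est$Q_PS
    est$k_KM <- gamma * est$Q_KM
    est$beta_PS <- conversion_factor(D_SI, est$D_V_PS)
    est$beta_KM <- conversion_factor(D_SI, est$D_V_KM)
  }
  reldif <- list()
  if (!is.null(est$Q_PS) && !is.null(est$Q_KM)) {
    reldif$Q <- rel_dif(est$Q_PS, est$Q_KM)
    reldif$D_V <- rel_dif(est$D_V_PS, est$D_V_KM)
    if (!is.null(est$k_PS)) {
      reldif$k <- rel_dif(est$k_PS, est$k_KM)
      reldif$beta <- rel_dif(est$beta_PS, est$beta_KM)
    }
  }
  structure(list(
    tau_M_samples = if (!is.null(markov)) attr(markov, "tau_M_samples") else NA,
    tau_M_seconds = if (!is.null(markov)) attr(markov, "tau_M_seconds") else NA,
    estimates = est, rel_dif = reldif,
    diagnostics = list(
      pawula_normalized = if (!is.null(km_branch)) km_branch$pawula else NA,
      km_bins = if (!is.null(km_branch)) km_branch$drift$n_bins else NA,
      ps_gof = if (!is.null(ps_branch)) ps_branch$fit$gof else NA,
      low_confidence = .low_confidence(est)),
    branches = list(markov = markov, km = km_branch, ps = ps_branch),
    errors = errors,
    unit = ts$unit, dt = ts$dt, n = ts$n,
    seed = ts$meta$seed),
    class = "ot_report")
}

## flag estimates whose own standard errors exceed 10% of the value
.low_confidence <- function(est) {
  checks <- c(Q_PS = "se_Q_PS", Q_KM = "se_Q_KM",
              D_V_PS = "se_D_V_PS", D_V_KM = "se_D_V_KM")
  flagged <- character(0)
  for (nm in names(checks)) {
    v <- est[[nm]]; s <- est[[checks[[nm]]]]
    if (!is.null(v) && !is.null(s) && is.finite(v) && is.finite(s) &&
        abs(s) > 0.1 * abs(v))
      flagged <- c(flagged, nm)
  }
  flagged
}

#' @export
print.ot_report <- function(x, ...) {
  e <- x$estimates
  cat("Calibration report\n")
  cat(sprintf("  record: n = %d, dt = %g (%s)\n", x$n, x$dt, x$unit))
  if (is.finite(x$tau_M_samples))
    cat(sprintf("  Markov-Einstein time scale: %d samples (%.4g s)\n",
                x$tau_M_samples, x$tau_M_seconds))
  fmt <- function(v, s) if (is.null(v)) "failed" else sprintf("%.5g +/- %.2g", v, s)
  cat(sprintf("  PS branch: Q = %s, D = %s\n",
              fmt(e$Q_PS, e$se_Q_PS), fmt(e$D_V_PS, e$se_D_V_PS)))
  cat(sprintf("  KM branch: Q = %s, D(0) = %s, b = %s\n",
              fmt(e$Q_KM, e$se_Q_KM), fmt(e$D_V_KM, e$se_D_V_KM),
              fmt(e$b_KM, e$se_b_KM)))
  if (!is.null(e$k_PS))
    cat(sprintf("  stiffness: PS %.5g, KM %.5g N/m; beta: PS %.5g, KM %.5g m/V\n",
                e$k_PS, e$k_KM, e$beta_PS, e$beta_KM))
  if (length(x$rel_dif))
    cat("  RelDif (%):", paste(sprintf("%s = %.1f", names(x$rel_dif),
                                       unlist(x$rel_dif)), collapse = ", "), "\n")
  if (length(x$diagnostics$low_confidence))
    cat("  LOW CONFIDENCE:", paste(x$diagnostics$low_confidence, collapse = ", "), "\n")
  if (length(x$errors))
    cat("  branch errors:", paste(names(x$errors), unlist(x$errors),
                                  sep = ": ", collapse = "; "), "\n")
  invisible(x)
}

#' Reference parameter sets for the synthetic validation suite
#'
#' The six trap models used throughout the validation studies: three linear
#' (`Q` = 1000, 3000, 5000 with `D0` = 50) and three with quadratic
#' diffusion (`(Q, D0, b)` = (7100, 52, 1040), (4100, 24, 506),
#' (1500, 2, 28)), chosen to be comparable with experimental values.
#'
#' @return A named list of [langevin_model()] objects.
#' @export
preset_models <- function() {
  list(linear_Q1000 = langevin_model(1000, 50),
       linear_Q3000 = langevin_model(3000, 50),
       linear_Q5000 = langevin_model(5000, 50),
       nonlinear_1 = langevin_model(7100, 52, 1040),
       nonlinear_2 = langevin_model(4100, 24, 506),
       nonlinear_3 = langevin_model(1500, 2, 28))
}

#' Run the synthetic validation suite
#'
#' Simulates the [preset_models()] (or any list of models), calibrates each
#' record with both branches, and tabulates true versus estimated
#' parameters. Supports ensemble averaging over several independent
#' records per model (inverse-variance weights; per-record reports are
#' retained).
#'
#' @param n samples per record.
#' @param dt sampling interval.
#' @param seed base seed; record `r` of model `i` uses
#'   `seed + 1000 * i + r`.
#' @param models named list of [langevin_model()]s.
#' @param config an [calibration_config()]; the Markov scan is skipped by
#'   default here (it is a per-record diagnostic, not a parameter
#'   estimate).
#' @param n_records ensemble size per model.
#' @return An object of class `ot_suite`: `summary` data frame (one row
#'   per model: true and estimated `Q`, `D`, `b` from both branches with
#'   standard errors and relative differences) and `reports`, the nested
#'   per-record reports.
#' @export
run_synthetic_suite <- function(n = 1e7, dt = 1e-6, seed = 1,
                                models = preset_models(),
                                config = calibration_config(markov = NULL),
                                n_records = 1) {
  stopifnot(n >= 100)
  rows <- list()
  reports <- list()
  ivw <- function(v, s) {       # inverse-variance weighted mean and its SE
    w <- 1 / s^2
    c(sum(w * v) / sum(w), sqrt(1 / sum(w)))
  }
  for (i in seq_along(models)) {
    model <- models[[i]]
    name <- names(models)[i]
    recs <- lapply(seq_len(n_records), function(r) {
      ts <- simulate_langevin(model, n = n, dt = dt,
                              seed = seed + 1000 * i + r)
      calibrate(ts, config)
    })
    reports[[name]] <- recs
    get <- function(field, se_field) {
      v <- vapply(recs, function(rp) rp$estimates[[field]] %||% NA_real_, 0)
      s <- vapply(recs, function(rp) rp$estimates[[se_field]] %||% NA_real_, 0)
      ok <- is.finite(v) & is.finite(s) & s > 0
      if (!any(ok)) return(c(NA_real_, NA_real_))
      if (sum(ok) == 1L) return(c(v[ok], s[ok]))
      ivw(v[ok], s[ok])
    }
    qps <- get("Q_PS", "se_Q_PS"); dps <- get("D_V_PS", "se_D_V_PS")
    qkm <- get("Q_KM", "se_Q_KM"); dkm <- get("D_V_KM", "se_D_V_KM")
    bkm <- get("b_KM", "se_b_KM")
    low <- unique(unlist(lapply(recs, function(rp) rp$diagnostics$low_confidence)))
    rows[[name]] <- data.frame(
      model = name, Q_true = model$Q, D0_true = model$D0, b_true = model$b,
      Q_PS = qps[1], se_Q_PS = qps[2], D_PS = dps[1], se_D_PS = dps[2],
      Q_KM = qkm[1], se_Q_KM = qkm[2], D_KM = dkm[1], se_D_KM = dkm[2],
      b_KM = bkm[1], se_b_KM = bkm[2],
      reldif_Q = rel_dif(qps[1], qkm[1]), reldif_D = rel_dif(dps[1], dkm[1]),
      low_confidence = paste(low, collapse = ","))
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reports = reports, n = n, dt = dt, seed = seed,
                 n_records = n_records),
            class = "ot_suite")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ot_suite <- function(x, ...) {
  cat(sprintf("Synthetic validation suite: n = %g, dt = %g, %d record(s) per model\n",
              x$n, x$dt, x$n_records))
  print(x$summary, digits = 4)
  invisible(x)
}

## strip non-serializable structure down to plain lists for JSON
.report_payload <- function(report) {
  list(tau_M_samples = report$tau_M_samples,
       tau_M_seconds = report$tau_M_seconds,
       estimates = report$estimates,
       rel_dif = report$rel_dif,
       diagnostics = report$diagnostics[c("pawula_normalized", "km_bins",
                                          "ps_gof", "low_confidence")],
       errors = report$errors,
       unit = report$unit, dt = report$dt, n = report$n,
       seed = report$seed)
}

#' Write a calibration report to JSON
#'
#' Serializes the estimates, relative differences, diagnostics and
#' provenance of an [calibrate()] report (full numeric precision). The
#' same function serializes an [calibration_config()], which round-trips
#' through [read_config()].
#'
#' @param x an `ot_report` or `ot_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  payload <- if (inherits(x, "ot_report")) {
    .report_payload(x)
  } else if (inherits(x, "ot_config")) {
    y <- unclass(x)
    if (!is.null(y$physical)) y$physical <- unclass(y$physical)
    y
  } else stop("unsupported object")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a serialized calibration configuration
#'
#' @param path JSON file written by [write_report()] from an `ot_config`.
#' @return An [calibration_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  physical <- NULL
  if (!is.null(raw$physical))
    physical <- physical_context(raw$physical$radius, raw$physical$viscosity,
                                 raw$physical$temperature)
  calibration_config(dt = raw$dt, unit = raw$unit, physical = physical,
                     km = raw$km %||% list(),
                     markov = if (is.null(raw$markov)) NULL else raw$markov,
                     ps = raw$ps %||% list(),
                     ensemble = raw$ensemble %||% list())
}
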